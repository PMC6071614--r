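attribute,value
name,cryptic
size_m,0.1
id_distance_m,1
approach_distance_m,0.7
perception_distance_m,
perception_angle_deg,360
max_acceleration_m_s2,0.1
max_sustained_speed_m_s,0.3
burst_speed_m_s,1.1

attribute,Guarding,Feeding,Nested,Patrolling
frequency,0.25,0.2,0.1,0.45
detectability,0.3,0.6,0.1,0.5
schooling,FALSE,FALSE,FALSE,FALSE
schooling_distance_bl,,,,
patch_distance_m,0.5,3,0.5,2
align,,,,
centre,,,,
spacing,,,,
wander,3,3,0,3
rest,2,1,15,2
cruise,0,0,0,0
patch_gathering,6,6,15,6
diver_avoidance,4,10,0,10
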