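attribute,value
name,bold
size_m,0.3
id_distance_m,6
approach_distance_m,3.0
perception_distance_m,
perception_angle_deg,320
max_acceleration_m_s2,0.1
max_sustained_speed_m_s,0.4
burst_speed_m_s,2.2

attribute,Wandering,Stationary
frequency,0.6,0.4
detectability,1,1
schooling,FALSE,FALSE
schooling_distance_bl,,
patch_distance_m,,
align,,
centre,,
spacing,,
wander,7,7
rest,0,6
cruise,10,0
patch_gathering,0,0
diver_avoidance,-1,0
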