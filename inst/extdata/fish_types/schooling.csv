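attribute,value
name,schooling
size_m,0.2
id_distance_m,4
approach_distance_m,1.0
perception_distance_m,0.35
perception_angle_deg,320
max_acceleration_m_s2,0.2
max_sustained_speed_m_s,0.5
burst_speed_m_s,2.6

attribute,Wandering,Feeding,Stationary
frequency,0.5,0.2,0.3
detectability,1,1,1
schooling,TRUE,TRUE,TRUE
schooling_distance_bl,1,1,1
patch_distance_m,,1,
align,5,1,5
centre,6,2,6
spacing,15,5,15
wander,3,1,1
rest,0,1,7
cruise,0,0,0
patch_gathering,0,10,0
diver_avoidance,10,10,10
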