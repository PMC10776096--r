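participant,max_dorsiflexion_deg,max_plantarflexion_deg,neutral_ankle_angle_deg
1,23,72,37
2,11,50,30
3,15,36,34
4,10,75,45
5,14,65,38
6,11,60,30
7,17,70,35
8,8,65,38
9,8,70,29
10,8,50,25
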