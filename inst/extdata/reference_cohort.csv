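id,age,sex,etiology,time_since_injury,lesion_level,ais,motor,sensory,pain
P02,50,m,Vehicle accident,9,Th4,B,50,200,none
P06,44,m,Gunshot,17,Th6,A,50,96,none
P08,38,m,Vehicle accident,16,Th8,A,50,104,none
P11,60,m,Vehicle accident,2,Th12,D,100,185,none
P12,50,m,Vehicle accident,4,Th11,A,60,148,none
P13,43,m,Vehicle accident,24,Th6,A,50,110,none
T01,25,m,Sports accident,2,C6/C7,D,71,134,none
T02,40,m,Vehicle accident,20,C5,C,38,126,none
T03,67,m,Vehicle accident,11,C4,D,95,170,none
T04,53,m,Gun shot,10,C4,B,27,102,none
T06,40,m,Vehicle accident,19,C6,B,24,78,none
T07,51,m,Vehicle accident,27,C6/C7,A,30,83,none
T08,35,m,Sports accident,5,C6/C7,D,93,176,none
T10,24,m,Vehicle accident,7,C6/C7,A,40,185,none
T13,69,m,Vehicle accident,10,C4/C5,C,79,200,none
P01,50,m,Vehicle accident,7,Th4/Th5,A,50,90,below_level
P03,35,m,Gunshot,12,Th4,B,50,144,below_level
P04,48,m,Vehicle accident,16,Th6/7,A,50,112,below_level
P05,44,m,Vehicle accident,26,Th7,B,50,168,below_level
P07,29,m,Sports accident,14,Th11,A,50,128,below_level
P09,29,f,Sports accident,5,L3,D,100,217,below_level
P10,65,m,Vehicle accident,33,Th12,A,50,158,below_level
P14,48,f,Hit by tree,19,L1,A,50,144,below_level
T05,57,m,Vehicle accident,6,C6/C7,D,96,202,below_level
T09,40,m,Vehicle accident,10,C7,D,96,160,below_level
T11,55,m,Vehicle accident,4,C3,D,89,104,below_level
T12,65,m,Vehicle accident,10,C6,D,88,220,below_level
T14,45,m,Vehicle accident,5,C2,D,100,224,below_level
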