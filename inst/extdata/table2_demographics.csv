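player_id,age,sex,days_since_injury,days_in_rehab,diagnosis,hemisphere,fim_motor,fim_cognition,fim_total,neglect_present,neglected_hemispace,clox,slct,alberts
9,52,male,53,6,TBI,bilateral,3.4,6.2,4.2,0,right,0,1,0
10,59,male,52,4,TBI,left,6.5,5.8,6.3,0,,0,0,0
11,37,male,37,7,TBI,left,6.6,5.0,6.2,0,,0,0,0
12,83,male,17,7,stroke,left,6.0,6.2,5.9,0,,0,0,0
13,65,female,22,6,ABI,right,5.0,5.6,5.1,0,,0,0,0
14,80,female,15,7,stroke,right,1.6,4.0,2.3,0,,0,0,0
15,70,male,23,14,ABI,left,2.3,4.4,2.9,0,,0,0,0
16,68,male,125,9,TBI,bilateral,1.2,2.2,1.5,0,,0,0,0
17,47,female,40,16,stroke,right,2.4,5.6,3.3,1,left,1,1,1
18,47,male,22,35,stroke,bilateral,5.3,7.0,5.8,0,,0,0,0
19,66,male,57,53,stroke,right,2.0,2.8,2.2,1,left,1,1,0
20,48,male,27,15,stroke,right,3.9,6.4,4.6,0,,0,0,0
21,41,female,42,3,stroke,right,1.5,5.4,2.6,1,left,0,1,0
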