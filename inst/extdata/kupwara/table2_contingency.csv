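factor,row_label,le_count,gt_count
gender,F,15,20
gender,M,54,13
place,Chuntiwari,7,13
place,Dudi,8,12
place,Indradhook,12,21
place,Khurhamma,4,8
place,Lalpora,10,12
place,Machil,6,8
place,Chota Bungus,9,10
place,Warnow,13,18
community,Dard,21,12
community,Kashmiri,19,12
community,Gujjar,9,29
education,Illiterate,15,18
education,Primary,8,5
education,Middle,18,5
education,Matric,11,3
education,SeniorSecondary,9,1
education,Graduate,8,1
age_category,<=30,22,0
age_category,31-40,9,0
age_category,41-50,12,6
age_category,51-60,12,8
age_category,61-70,10,11
age_category,71-80,4,8
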