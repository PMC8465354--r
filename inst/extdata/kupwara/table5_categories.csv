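category,label,n_t,pct_nt_printed,n_ur,pct_nur_printed,icf_printed
GAS,Gastrointestinal problems,28,26.17,262,16.19,0.9
CAR,Cardiovascular problems,13,12.15,155,9.58,0.92
DER,Dermatological disorders,19,17.76,203,12.55,0.91
GYN,Gynecological problems,9,8.41,101,6.24,0.92
NER,Nervous system disorders,6,5.61,74,4.57,0.93
PAR,Parasitic problems,1,0.93,7,0.43,1.0
CAN,Cancer,10,9.35,132,8.16,0.93
RES,Respiratory complaints,29,27.1,243,15.02,0.88
SKE,Skeleto-muscular system disorders,21,19.63,175,10.82,0.89
MET,Metabolic syndromes,6,5.61,70,4.33,0.93
ETH,Ethnoveterinary ailments,7,6.54,40,2.47,0.85
EY,Energy yielding,5,4.67,56,3.46,0.93
ENT,"Eyes, ears and nose problems",6,5.61,53,3.28,0.9
FVR,Fever issues,6,5.61,54,3.34,0.91
IB,Insect bites,1,0.93,6,0.37,1.0
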