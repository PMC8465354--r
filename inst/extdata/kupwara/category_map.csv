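ailment,category
hepatotoxic,GAS
ulcer,GAS
choleretic,GAS
constipation,GAS
indigestion,GAS
dysentery,GAS
diarrhea,GAS
excess gas,GAS
heartburn,GAS
nausea,GAS
stomach pain,GAS
vomiting,GAS
kidney stone,GAS
blood purifier,CAR
heart disorders,CAR
heart attack,CAR
stroke,CAR
abscess,DER
eczema,DER
acne,DER
itching,DER
ringworm,DER
alopecia,DER
blemishes,DER
leukoderma,DER
dandruff,DER
boils,DER
cuts,DER
burns,DER
scabies,DER
wounds,DER
abortifacient,GYN
oxytocic,GYN
uterine hemorrhage,GYN
menstrual problem,GYN
genital tract problems,GYN
lactation in women,GYN
anxiety,NER
psychosis,NER
major depressive disorder,NER
narcolepsy,NER
neuropathic pain,NER
vascular dementia,NER
antihelminthic,PAR
cancer,CAN
persistent cough,CAN
loss in weight,CAN
fatigue,CAN
asthma,RES
bronchitis,RES
common cold,RES
pneumonia,RES
shortness of breathing,RES
allergies,RES
tuberculosis,RES
swelling,SKE
arthritis,SKE
rheumatic pain,SKE
neck pain,SKE
back pain,SKE
muscle pain,SKE
joint inflammation,SKE
bone fracture,SKE
obesity,MET
diabetes,MET
blood pressure,MET
excessive body fat,MET
abnormal cholesterol,MET
jaundice,MET
veterinary wounds,ETH
veterinary stomach problems,ETH
milk yielding problems,ETH
tonic,EY
laxative,EY
throat pain,ENT
toothache,ENT
sinus infection,ENT
ear inflammation,ENT
malaria,FVR
typhoid,FVR
high body temperature,FVR
fever,FVR
bee sting,IB
scorpion sting,IB
insect bite,IB
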