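informant_id,taxon_id,ailment,category,village,count
,t001,,GAS,,11
,t001,,CAR,,18
,t002,,CAR,,16
,t003,,GAS,,12
,t004,,RES,,8
,t004,,GAS,,11
,t005,,CAR,,10
,t005,,RES,,18
,t005,,GAS,,5
,t006,,RES,,9
,t006,,MET,,3
,t007,,CAR,,13
,t007,,DER,,14
,t007,,RES,,10
,t008,,GYN,,36
,t009,,GAS,,9
,t009,,GYN,,4
,t010,,SKE,,17
,t010,,FVR,,5
,t011,,CAN,,21
,t011,,DER,,13
,t011,,GYN,,11
,t012,,SKE,,2
,t013,,EY,,11
,t014,,RES,,9
,t014,,SKE,,5
,t015,,DER,,12
,t016,,DER,,13
,t017,,SKE,,8
,t017,,ETH,,4
,t018,,FVR,,10
,t019,,GAS,,24
,t020,,CAR,,12
,t020,,DER,,11
,t021,,CAN,,8
,t021,,MET,,11
,t021,,SKE,,7
,t022,,GAS,,16
,t023,,GAS,,2
,t023,,PAR,,7
,t024,,DER,,7
,t024,,GYN,,2
,t024,,ETH,,6
,t025,,GAS,,16
,t025,,ETH,,5
,t026,,RES,,3
,t027,,SKE,,4
,t027,,GAS,,7
,t027,,DER,,13
,t027,,RES,,6
,t028,,DER,,17
,t028,,EY,,13
,t029,,RES,,14
,t029,,SKE,,6
,t030,,MET,,9
,t030,,SKE,,4
,t030,,CAN,,11
,t031,,CAN,,12
,t031,,RES,,2
,t032,,DER,,12
,t033,,GAS,,20
,t034,,RES,,5
,t035,,ETH,,8
,t035,,SKE,,4
,t036,,MET,,33
,t037,,NER,,16
,t038,,CAR,,2
,t039,,SKE,,2
,t040,,DER,,31
,t040,,SKE,,16
,t041,,CAR,,5
,t042,,MET,,4
,t042,,SKE,,9
,t043,,CAN,,16
,t044,,GAS,,8
,t045,,GAS,,5
,t045,,SKE,,2
,t046,,RES,,4
,t047,,RES,,9
,t048,,GAS,,7
,t049,,FVR,,12
,t050,,ENT,,7
,t050,,SKE,,9
,t051,,DER,,4
,t052,,SKE,,23
,t053,,GAS,,19
,t053,,ETH,,13
,t054,,CAR,,21
,t055,,RES,,12
,t056,,ETH,,5
,t056,,MET,,3
,t057,,CAN,,8
,t058,,GAS,,7
,t058,,FVR,,5
,t059,,GAS,,5
,t060,,RES,,3
,t061,,GAS,,2
,t062,,DER,,3
,t063,,ENT,,3
,t064,,CAN,,21
,t065,,GYN,,9
,t065,,RES,,7
,t066,,GAS,,13
,t067,,CAN,,13
,t068,,NER,,12
,t069,,NER,,10
,t070,,GAS,,16
,t070,,SKE,,11
,t071,,CAR,,12
,t072,,DER,,11
,t073,,IB,,6
,t073,,GAS,,2
,t074,,GAS,,4
,t075,,CAR,,17
,t076,,MET,,10
,t077,,RES,,18
,t077,,EY,,17
,t078,,CAN,,15
,t078,,CAR,,8
,t078,,SKE,,10
,t079,,DER,,3
,t079,,ENT,,9
,t079,,RES,,3
,t080,,GYN,,13
,t081,,RES,,7
,t081,,GYN,,11
,t082,,CAR,,13
,t082,,NER,,4
,t083,,GYN,,2
,t083,,DER,,9
,t084,,ETH,,3
,t084,,RES,,9
,t085,,CAR,,21
,t085,,DER,,3
,t086,,RES,,15
,t087,,RES,,12
,t088,,ENT,,13
,t088,,GAS,,2
,t089,,RES,,4
,t090,,RES,,11
,t091,,RES,,8
,t091,,EY,,4
,t092,,GAS,,9
,t093,,RES,,8
,t094,,RES,,7
,t095,,ETH,,2
,t095,,RES,,6
,t095,,SKE,,2
,t096,,DER,,4
,t096,,GAS,,5
,t097,,ENT,,14
,t097,,GAS,,11
,t097,,FVR,,4
,t098,,GYN,,13
,t099,,DER,,7
,t099,,SKE,,9
,t100,,NER,,21
,t101,,CAN,,7
,t102,,SKE,,16
,t103,,RES,,5
,t103,,FVR,,18
,t104,,RES,,11
,t105,,GAS,,9
,t106,,DER,,16
,t106,,NER,,11
,t107,,GAS,,4
,t107,,EY,,11
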