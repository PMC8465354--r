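taxon_id,botanical_name,ur_printed,fq_printed,ri_printed
t001,Morchella esculenta (L.) Pers.,29,28.43,35.23
t002,Asplenium crinicaule Hance,16,15.69,38.64
t003,Equisetum arvense L.,12,11.76,87.50
t004,Adiantum capillus-veneris L.,19,18.63,26.14
t005,Acorus calamus L.,33,32.35,39.77
t006,Allium sativum L.,12,11.76,43.18
t007,Arisaema jacquemontii Blume,37,36.27,57.95
t008,Asparagus racemosus Willd.,36,35.29,47.73
t009,Dioscorea deltoidea Wall.ex Griseb.,13,12.75,43.18
t010,Iris kashmiriana Baker,22,21.57,48.86
t011,Fritillaria cirrhosa D.Don,45,44.12,48.86
t012,Notholirion thomsonianum (Royle) Stapf.,2,1.96,26.14
t013,Avena fatua L.,11,10.78,34.09
t014,Cynodon dactylon (L.) Pers.,14,13.73,35.23
t015,Oryza sativa L.,12,11.76,53.41
t016,Sorghum halepense (L.) Pers.,13,12.75,35.23
t017,Sambucus wightiana Wall. ex Wight & Arn.,12,11.76,34.09
t018,Amaranthus viridis L.,10,9.80,44.32
t019,Trachyspermum ammi (L.) Sprague,24,23.53,35.23
t020,Arctium lappa L.,23,22.55,39.77
t021,Artemisia absinthium L.,26,25.49,48.86
t022,Artemisia brevifolia Wall. ex DC.,16,15.69,53.41
t023,Artemisia imponens Pamp.,9,8.82,44.32
t024,Cichorium intybus L.,15,14.71,53.41
t025,Dolomiaea macrocephala DC. ex Royle,21,20.59,26.14
t026,Matricaria chamomilla L.,3,2.94,48.86
t027,Dolomiaea costus (Falc.) Kasana & A.K.Pandey,26,25.49,65.91
t028,Taraxacum officinale F.W. Wigg.,30,29.41,62.50
t029,Berberis aristata DC.,20,19.61,44.32
t030,Podophyllum hexandrum Royle,24,23.53,53.41
t031,Arnebia benthamii (Wall. ex G. Don) I.M. Johnst.,14,13.73,48.86
t032,Hackelia uncinata (Royle ex Benth.) C.E.C. Fisch.,12,11.76,35.23
t033,Capsella bursa-pastoris (L.) Medik.,20,19.61,53.41
t034,Cardamine impatiens L.,5,4.90,39.77
t035,Nasturtium officinale W.T.Aiton,12,11.76,56.82
t036,Codonopsis rotundifolia Benth.,33,32.35,51.14
t037,Cannabis sativa L.,16,15.69,56.82
t038,Celtis australis L.,2,1.96,48.86
t039,Dipsacus inermis Wall.,2,1.96,26.14
t040,Valeriana jatamansi Jones ex Roxb.,47,46.08,56.82
t041,Stellaria media (L.) Vill.,5,4.90,47.73
t042,Cuscuta cassytoides Nees ex Engelm.,13,12.75,26.14
t043,Rhodiola himalensis (D.Don) S.H.Fu.,16,15.69,90.91
t044,Solena amplexicaulis (Lam.) Gandhi,8,7.84,38.64
t045,Euphorbia royleana Boiss.,7,6.86,52.27
t046,Indigofera heterantha Wall. ex Brandis,4,3.92,26.14
t047,Trifolium repens L.,9,8.82,53.41
t048,Trigonella foenum-graecum L.,7,6.86,39.77
t049,Gentiana kurrao Royle,12,11.76,69.32
t050,Geranium wallichianum D.Don ex Sweet,16,15.69,21.59
t051,Parrotiopsis jacquemontiana (Decne.) Rehder,4,3.92,56.82
t052,Juglans regia L.,23,22.55,39.77
t053,Ajuga bracteosa Buch.-Ham. ex. D. Don,32,31.37,38.64
t054,Lamium album L.,21,20.59,69.32
t055,Mentha piperita L.,12,11.76,53.41
t056,Nepeta cataria L.,8,7.84,52.27
t057,Prunella vulgaris L.,8,7.84,30.68
t058,Thymus linearis Benth.,12,11.76,60.23
t059,Abutilon indicum (L.) Sweet,5,4.90,46.59
t060,Alcea rosea L.,3,2.94,26.14
t061,Eriolaena candollei Wall.,2,0.98,30.68
t062,Malva cashemiriana (Cambess.) Alef.,3,2.94,35.23
t063,Malva sylvestris L.,3,2.94,61.36
t064,Trillium govanianum Wall. ex D.Don,21,20.59,35.23
t065,Ficus carica L.,16,15.69,56.82
t066,Morus alba L.,13,12.75,48.86
t067,Corydalis govaniana Wall.,13,12.75,35.23
t068,Papaver somniferum L.,12,11.76,44.32
t069,Phytolacca acinosa Roxb.,10,9.80,35.23
t070,Picrorhiza kurroa Royle ex Benth.,27,26.47,26.14
t071,Plantago lanceolata L.,12,11.76,44.32
t072,Wulfeniopsis amherstiana (Benth.) D.Y.Hong,11,10.78,48.86
t073,Persicaria hydropiper (L.) Delarbre,8,7.84,21.59
t074,Persicaria mitis (Schrank) Assenov,4,3.92,21.59
t075,Rheum australe D.Don,17,16.67,43.18
t076,Rheum emodi D.Don,10,9.80,26.14
t077,Rumex acetosa L.,35,34.31,44.32
t078,Portulaca oleracea L.,33,32.35,21.59
t079,Lysimachia arvensis (L.) U.Manns & Anderb.,15,14.71,47.73
t080,Aconitum chasmanthum Stapf ex Holmes,13,12.75,78.41
t081,Aconitum heterophyllum Wall. ex Royle,18,17.65,47.73
t082,Anemonastrum obtusilobum (D.Don) Mosyakin,17,6.86,55.68
t083,Aquilegia vulgaris L.,11,10.78,48.86
t084,Ranunculus hirtellus Royle,12,11.76,53.41
t085,Zizyphus mauritiama Lam.,24,20.59,30.68
t086,Cormus domestica (L.) Spach,15,14.71,48.86
t087,Cydonia oblonga Mill.,12,11.76,44.32
t088,Fragaria vesca L.,15,14.71,44.32
t089,Geum elatum Wall. ex G.Don,4,3.92,48.86
t090,Potentilla indica (Andrews) Teschem,11,10.78,47.73
t091,Rosa webbiana Wall. ex Royle,12,11.76,53.41
t092,Galium aparine L.,9,8.82,26.14
t093,Verbascum thapsus L.,8,7.84,35.23
t094,Populus alba L.,7,6.86,73.86
t095,Salix alba L.,10,9.80,21.59
t096,Aesculus indica Wall.ex Cambess.,9,8.82,26.14
t097,Bergenia ciliata (Haw.) Sternb.,29,28.43,39.77
t098,Atropa acuminata Royle ex Lindl.,13,12.75,38.64
t099,Datura stramonium L.,16,15.69,44.32
t100,Hyoscyamus niger L.,21,20.59,30.68
t101,Solanum pseudocapsicum L.,7,6.86,30.68
t102,Urtica dioica L.,16,15.69,48.86
t103,Viola odorata L.,23,22.55,55.68
t104,Vitis vinifera L.,11,10.78,39.77
t105,Juniperus communis L.,9,8.82,65.91
t106,Cedrus deodara (Roxb. ex D.Don) G.Don,27,26.47,47.73
t107,Pinus roxburghii Sarg.,15,14.71,44.32
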