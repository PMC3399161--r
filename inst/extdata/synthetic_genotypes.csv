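6,30,3
ramet_id,site_id,elevation_mm,height_cm,TA3,,TA5,,TA7,,TA8,,TA16,,TA20,
R0001,S01,34,166.41659515533161,102,110,142,150,182,192,220,228,264,268,300,308
R0002,S01,214,154.43734139996891,102,108,142,150,186,192,226,228,264,268,302,314
R0003,S01,-41,162.77373125250722,102,108,142,150,186,192,226,228,264,268,302,314
R0004,S01,131,132.51409845871495,102,114,146,152,186,194,224,228,260,268,300,310
R0005,S01,70,154.00234059976569,108,110,142,154,188,190,228,234,268,268,308,310
R0006,S01,131,164.19152291752559,104,104,144,144,180,186,224,226,264,264,300,306
R0007,S01,0,167.1545171088045,104,104,144,144,180,186,224,226,264,264,300,306
R0008,S01,46,163.97425988644068,104,104,144,144,180,186,224,226,264,274,300,306
R0009,S01,-1,150.52549058450356,104,104,144,144,180,186,224,226,264,264,300,306
R0010,S01,-129,154.34917535257176,100,100,142,142,180,184,224,224,262,264,302,306
R0011,S02,-256,152.95829149030681,108,112,148,154,188,188,230,232,268,270,308,310
R0012,S02,-174,99.184648406113567,108,112,148,154,188,188,230,232,268,270,308,310
R0013,S02,-123,163.29958542418683,100,102,144,146,184,186,224,224,260,260,302,306
R0014,S02,-105,171.94306970025806,100,102,144,146,184,186,224,224,260,260,302,306
R0015,S02,-41,176.2503641379561,100,102,144,146,184,186,224,224,260,260,302,306
R0016,S02,-5,181.8451032967676,100,102,144,146,184,186,224,224,260,260,302,306
R0017,S02,-191,128.63068727350407,100,100,140,146,180,186,220,224,260,264,300,300
R0018,S02,-59,110.94371007627794,100,100,140,146,180,186,220,224,260,264,300,300
R0019,S02,-279,177.40603563700685,100,100,140,146,180,186,220,224,260,264,300,300
R0020,S02,-124,164.49110403790979,100,100,140,146,180,186,220,224,260,264,300,300
R0021,S03,150,145.09303046916929,108,114,148,150,188,190,228,232,268,268,310,314
R0022,S03,272,161.81073628764284,108,114,148,150,188,190,228,232,268,268,310,314
R0023,S03,207,180.55462498450561,106,108,144,148,186,192,226,228,260,268,306,310
R0024,S03,279,167.87427004328808,106,108,144,148,186,192,226,228,260,268,306,310
R0025,S03,326,156.44672213628951,104,108,146,148,186,188,226,234,264,268,306,314
R0026,S03,344,128.39672961206719,104,108,146,148,186,188,226,234,264,268,306,314
R0027,S03,294,167.05666794424278,104,108,146,148,186,188,226,234,264,268,306,314
R0028,S03,274,137.68570199382842,104,108,144,148,184,192,220,232,266,274,304,314
R0029,S03,324,159.38595164770769,114,114,150,154,192,192,228,228,268,274,314,314
R0030,S03,346,118.57428916988123,114,114,150,154,192,192,228,228,268,274,314,314
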