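locus,allele,species
TA3,100,A
TA3,102,A
TA3,104,A
TA3,106,A
TA3,108,B
TA3,110,B
TA3,112,B
TA3,114,B
TA5,140,A
TA5,142,A
TA5,144,A
TA5,146,A
TA5,148,B
TA5,150,B
TA5,152,B
TA5,154,B
TA7,180,A
TA7,182,A
TA7,184,A
TA7,186,A
TA7,188,B
TA7,190,B
TA7,192,B
TA7,194,B
TA8,220,A
TA8,222,A
TA8,224,A
TA8,226,A
TA8,228,B
TA8,230,B
TA8,232,B
TA8,234,B
TA16,260,A
TA16,262,A
TA16,264,A
TA16,266,A
TA16,268,B
TA16,270,B
TA16,272,B
TA16,274,B
TA20,300,A
TA20,302,A
TA20,304,A
TA20,306,A
TA20,308,B
TA20,310,B
TA20,312,B
TA20,314,B
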