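tube_id,agarose_pct,ni_mM,t1_1p4T_ms,t1_1p5T_ms,t1_3T_ms,t2_1p4T_ms,t2_1p5T_ms,t2_3T_ms
A,1.261,3.139,821,803,807,40,35,34
B,0.969,2.511,978,982,988,50,43,41
C,0.773,2.639,1122,1073,1137,48,42,40
D,0.821,1.775,1083,1090,1130,71,60,59
E,0.649,1.791,1237,1225,1228,70,61,59
F,0.882,2.081,1030,1015,1019,60,52,50
G,0.594,1.562,1295,1287,1302,82,70,68
H,0.664,2.139,1221,1182,1217,60,52,51
I,2.840,2.502,440,435,445,47,41,40
outer,1.155,0.780,850,,,140,,
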