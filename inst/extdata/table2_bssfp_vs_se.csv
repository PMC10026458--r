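tube_id,field_t,t2_bssfp_ms,t2_se_ms,printed_diff_ms,printed_pct
A,1.5,43,35,8,23
B,1.5,49,43,6,14
C,1.5,47,42,5,12
D,1.5,65,60,5,8
E,1.5,65,61,4,7
F,1.5,57,52,5,10
G,1.5,74,70,4,6
H,1.5,57,52,5,10
I,1.5,56,41,15,37
A,3,43,34,9,27
B,3,48,41,7,17
C,3,45,40,5,13
D,3,65,59,6,10
E,3,65,59,6,10
F,3,57,50,7,14
G,3,72,68,4,6
H,3,56,51,5,10
I,3,56,40,16,40
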