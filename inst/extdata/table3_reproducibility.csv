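tube_id,field_t,t2_baseline_ms,t2_repeat_ms,printed_abs_diff_ms,printed_pct_diff
A,1.5,43,43,0,0
B,1.5,49,49,0,0
C,1.5,47,47,0,0
D,1.5,65,66,1,1.5
E,1.5,65,65,0,0
F,1.5,57,57,0,0
G,1.5,74,73,1,1.4
H,1.5,57,57,0,0
I,1.5,56,57,1,1.8
A,3,43,43,0,0
B,3,48,49,1,2.1
C,3,45,45,0,0
D,3,65,65,0,0
E,3,65,65,0,0
F,3,57,57,0,0
G,3,72,71,1,1.4
H,3,56,56,0,0
I,3,56,57,1,1.8
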