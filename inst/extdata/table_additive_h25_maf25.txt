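#order=2
#maf=0.25,0.25
0,0	0.000884422721489
0,1	0.0051285538331
0,2	0.0297392454761
1,0	0.0051285538331
1,1	0.0297392454761
1,2	0.172450704481
2,0	0.0297392454761
2,1	0.172450704481
2,2	            1
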