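#order=2
#maf=0.25,0.25
0,0	0.36476426799
0,1	0.36476426799
0,2	0.36476426799
1,0	0.36476426799
1,1	            1
1,2	            1
2,0	0.36476426799
2,1	            1
2,2	            1
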