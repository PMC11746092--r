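#order=2
#maf=0.25,0.25
0,0	0.00675264500822
0,1	0.00675264500822
0,2	0.00675264500822
1,0	0.00675264500822
1,1	0.0235562111937
1,2	0.0821744790566
2,0	0.00675264500822
2,1	0.0821744790566
2,2	            1
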