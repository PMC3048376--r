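TR:TGFa,TR:TNFa,TR:PI3K:i,TR:MEK:i,DV:Akt,DV:ERK,DV:Hsp27,DV:JNK,DV:NFkB,DV:p38
0,0,0,0,0,0,0,0,0,0
1,0,0,0,0.380952380952381,0.896687960687961,0,0.211184275184275,0,0
0,1,0,0,0,0,0.912888888888889,0.8,0.8,0.6
1,1,0,0,0.380952380952381,0.896687960687961,0.912888888888889,0.8,0.8,0.6
0,0,1,0,0,0,0,0,0,0
1,0,1,0,0,0.896687960687961,0,0,0,0
0,1,1,0,0,0,0.912888888888889,0.8,0.8,0.6
1,1,1,0,0,0.896687960687961,0.912888888888889,0.8,0.8,0.6
0,0,0,1,0,0,0,0,0,0
1,0,0,1,0.380952380952381,0,0,0.211184275184275,0,0
0,1,0,1,0,0,0.912888888888889,0.8,0.8,0.6
1,1,0,1,0.380952380952381,0,0.912888888888889,0.8,0.8,0.6
0,0,1,1,0,0,0,0,0,0
1,0,1,1,0,0,0,0,0,0
0,1,1,1,0,0,0.912888888888889,0.8,0.8,0.6
1,1,1,1,0,0,0.912888888888889,0.8,0.8,0.6
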