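el_low,el_high,separation_deg
-45,30,75
-30,45,75
-15,60,75
0,75,75
-40,20,60
-25,35,60
-10,50,60
5,65,60
15,75,60
-45,0,45
30,75,45
-30,15,45
-40,5,45
20,65,45
-15,15,30
45,75,30
-45,-15,30
-25,5,30
35,65,30
-30,-15,15
0,15,15
60,75,15
-40,-25,15
50,65,15
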