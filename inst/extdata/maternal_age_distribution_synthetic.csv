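age,prob
14,0
15,0
16,0.00515798968402063
17,0.0108139783720433
18,0.0165249669500661
19,0.02249795500409
20,0.0284709430581139
21,0.0341129317741364
22,0.0390919218161564
23,0.043498913002174
24,0.0475489049021902
25,0.0511068977862044
26,0.0540348919302161
27,0.0561948876102248
28,0.0577248845502309
29,0.0587148825702349
30,0.0589608820782358
31,0.058256883486233
32,0.0563988872022256
33,0.0529648940702119
34,0.0480929038141924
35,0.0424139151721697
36,0.0365559268881462
37,0.0311519376961246
38,0.0259229481541037
39,0.0204499591000818
40,0.0151479697040606
41,0.0104329791340417
42,0.00671898656202688
43,0.00429699140601719
44,0.00288999422001156
45,0.00206199587600825
46,0.00137999724000552
47,0.000406999186001628
48,0
49,0
50,0
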