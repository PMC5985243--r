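"age","q"
0,0.000526861159890646
1,0.00052963968655495
2,0.000532704289104902
3,0.000536084420770799
4,0.000539812566949571
5,0.000543924557314113
6,0.000548459910038934
7,0.000553462211443478
8,0.000558979534696302
9,0.000565064901594359
10,0.000571776791845391
11,0.000579179704734645
12,0.000587344778558818
13,0.000596350473761498
14,0.000606283326310519
15,0.000617238778531592
16,0.000629322095346163
17,0.000642649374678617
18,0.00065734866168965
19,0.000673561177484516
20,0.000691442674024989
21,0.000711164928175467
22,0.000732917389127286
23,0.000756908994895555
24,0.000783370175178044
25,0.000812555059618858
26,0.00084474391244993
27,0.00088024581660473
28,0.000919401632728634
29,0.000962587261074566
30,0.00101021723708195
31,0.00106274869452894
32,0.0011206857335313
33,0.00118458423438039
34,0.00125505716227936
35,0.00133278041249674
36,0.00141849925033222
37,0.00151303540562076
38,0.00161729488732398
39,0.00173227659010722
40,0.00185908177172323
41,0.00199892448754613
42,0.00215314307678116
43,0.00232321280373537
44,0.002510759767129
45,0.00271757620077839
46,0.00294563730012531
47,0.00319711972104597
48,0.00347442191016123
49,0.00378018643947975
50,0.00411732453263225
51,0.00448904298514019
52,0.00489887369704878
53,0.00535070605271981
54,0.0058488223994666
55,0.00639793689380708
56,0.00700323800109759
57,0.00767043495080766
58,0.00840580846518868
59,0.00921626609290971
60,0.0101094024905644
61,0.011093565002726
62,0.0121779248941449
63,0.0133725545841097
64,0.01468851122093
65,0.0161379269114933
66,0.0177341058839042
67,0.0194916288067094
68,0.0214264644117872
69,0.0235560884643933
70,0.0258996099868756
71,0.0284779044648232
72,0.0313137535372162
73,0.0344319903853665
74,0.0378596496773769
75,0.0416261204820623
76,0.0457633000235987
77,0.0503057454886179
78,0.0552908203024759
79,0.0607588303410609
80,0.0667531444180807
81,0.0733202920647033
82,0.0805100300796299
83,0.0883753675575526
84,0.096972537093133
85,0.106360897606919
86,0.11660275176493
87,0.127763058302849
88,0.13990901678708
89,0.153109499557513
90,0.167434302963696
91,0.182953187758877
92,0.199734676972413
93,0.217844579160921
94,0.237344206183389
95,0.258288258230407
96,0.280722355577967
97,0.304680207379767
98,0.330180423808896
99,0.357223000100521
100,0.385785530552617
101,0.415819248093155
102,0.447245030914738
103,0.479949571388084
104,0.513781962231512
105,0.548551017242846
106,0.584023703059251
107,0.619925105980062
108,0.655940382536953
109,0.691719130188969
110,1
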