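"age","weight"
16,0.01
17,0.01
18,0.01
19,0.01
20,0.017
21,0.017
22,0.017
23,0.017
24,0.017
25,0.017
26,0.017
27,0.017
28,0.017
29,0.017
30,0.017
31,0.017
32,0.017
33,0.017
34,0.017
35,0.017
36,0.017
37,0.017
38,0.017
39,0.017
40,0.017
41,0.017
42,0.017
43,0.017
44,0.017
45,0.017
46,0.017
47,0.017
48,0.017
49,0.017
50,0.017
51,0.017
52,0.017
53,0.017
54,0.017
55,0.017
56,0.017
57,0.017
58,0.017
59,0.017
60,0.015
61,0.015
62,0.015
63,0.015
64,0.015
65,0.015
66,0.015
67,0.015
68,0.015
69,0.015
70,0.009
71,0.009
72,0.009
73,0.009
74,0.009
75,0.009
76,0.009
77,0.009
78,0.009
79,0.009
80,0.00363636363636364
81,0.00363636363636364
82,0.00363636363636364
83,0.00363636363636364
84,0.00363636363636364
85,0.00363636363636364
86,0.00363636363636364
87,0.00363636363636364
88,0.00363636363636364
89,0.00363636363636364
90,0.00363636363636364
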