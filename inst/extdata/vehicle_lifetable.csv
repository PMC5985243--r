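"vehicle_age","expire_prob"
0,8.08140210306618e-06
1,0.000121214174334083
2,0.000525155316902004
3,0.00141325150081384
4,0.00297760753262155
5,0.00540796673491017
6,0.00889023150950818
7,0.0136046407863734
8,0.0197236298107427
9,0.0274094080303691
10,0.0368113023950634
11,0.0480629257462208
12,0.0612792426165161
13,0.0765536170330717
14,0.0939549380795597
15,0.113524928210762
16,0.135275745777586
17,0.159187996071217
18,0.185209263656959
19,0.213253272193995
20,0.243199765873604
21,0.274895188861177
22,0.308154215819302
23,0.342762158204096
24,0.37847823843393
25,0.415039688481201
26,0.452166592537976
27,0.489567357044864
28,0.526944657627899
29,0.564001683499555
30,0.600448477699323
31,0.636008157978889
32,0.67042279957222
33,0.703458768374879
34,0.734911311369857
35,1
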