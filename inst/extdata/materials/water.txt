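# name: water
# density_g_cm3: 0.998
# z_eff: 7.4167
energy_keV,mu_pe_per_mm,mu_compton_per_mm,mu_rayleigh_per_mm
16,0.1033408,0.02090847,0.01135153
17,0.08476482,0.02083455,0.0103934
18,0.07032012,0.02076133,0.009554338
19,0.05892932,0.02068879,0.008814982
20,0.04983345,0.02061693,0.008159816
21,0.04248773,0.02054572,0.007576272
22,0.0364946,0.02047517,0.007054082
23,0.03155946,0.02040526,0.006584782
24,0.02746101,0.02033599,0.006161344
25,0.02403089,0.02026735,0.005777891
26,0.02113958,0.02019932,0.00542947
27,0.01868633,0.02013191,0.005111886
28,0.01659207,0.0200651,0.004821563
29,0.0147941,0.01999888,0.004555435
30,0.01324236,0.01993325,0.004310862
31,0.01189654,0.01986819,0.004085558
32,0.01072392,0.01980371,0.003877536
33,0.009697799,0.01973979,0.003685062
34,0.00879624,0.01967643,0.003506615
35,0.008001095,0.01961362,0.003340858
36,0.00729728,0.01955134,0.003186611
37,0.006672189,0.0194896,0.003042829
38,0.006115232,0.01942839,0.002908583
39,0.005617471,0.0193677,0.002783047
40,0.005171331,0.01930753,0.002665481
41,0.004770362,0.01924786,0.002555223
42,0.00440905,0.0191887,0.002451679
43,0.004082664,0.01913002,0.002354315
44,0.003787129,0.01907184,0.002262649
45,0.003518925,0.01901414,0.002176243
46,0.003274998,0.01895692,0.002094703
47,0.003052693,0.01890016,0.002017671
48,0.002849692,0.01884388,0.00194482
49,0.002663968,0.01878805,0.001875853
50,0.002493741,0.01873267,0.001810499
51,0.002337446,0.01867774,0.001748511
52,0.002193703,0.01862325,0.001689662
53,0.002061289,0.01856921,0.001633743
54,0.001939124,0.01851559,0.001580563
55,0.001826245,0.0184624,0.001529948
56,0.001721797,0.01840962,0.001481733
57,0.001625015,0.01835727,0.001435772
58,0.001535218,0.01830533,0.001391925
59,0.001451792,0.01825379,0.001350065
60,0.00137419,0.01820265,0.001310075
61,0.001301918,0.01815191,0.001271844
62,0.001234531,0.01810157,0.001235271
63,0.001171627,0.01805161,0.001200263
64,0.001112845,0.01800203,0.001166731
65,0.001057856,0.01795283,0.001134594
66,0.001006363,0.017904,0.001103776
67,0.0009580947,0.01785555,0.001074206
68,0.0009128061,0.01780746,0.001045817
69,0.0008702732,0.01775973,0.001018548
70,0.000830292,0.01771235,0.0009923413
71,0.0007926763,0.01766533,0.0009671418
72,0.0007572556,0.01761866,0.0009428992
73,0.0007238739,0.01757233,0.0009195658
74,0.0006923884,0.01752635,0.0008970969
75,0.0006626678,0.0174807,0.0008754505
76,0.0006345917,0.01743538,0.0008545872
77,0.000608049,0.0173904,0.0008344698
78,0.0005829379,0.01734574,0.0008150633
79,0.0005591642,0.0173014,0.0007963348
80,0.0005366409,0.01725738,0.0007782532
81,0.0005152881,0.01721367,0.0007607893
82,0.0004950314,0.01717028,0.0007439154
83,0.0004758023,0.01712719,0.0007276053
84,0.0004575372,0.01708441,0.0007118343
85,0.0004401772,0.01704193,0.0006965791
86,0.0004236674,0.01699975,0.0006818176
87,0.0004079571,0.01695787,0.0006675287
88,0.0003929991,0.01691627,0.0006536927
89,0.0003787493,0.01687497,0.0006402907
90,0.0003651669,0.01683395,0.0006273049
91,0.0003522137,0.01679321,0.0006147184
92,0.0003398541,0.01675275,0.000602515
93,0.0003280549,0.01671257,0.0005906794
94,0.000316785,0.01667266,0.0005791971
95,0.0003060154,0.01663302,0.0005680543
96,0.0002957191,0.01659365,0.0005572379
97,0.0002858706,0.01655454,0.0005467352
98,0.0002764461,0.0165157,0.0005365343
99,0.0002674233,0.01647712,0.000526624
100,0.0002587812,0.01643879,0.0005169932
101,0.0002505004,0.01640072,0.0005076318
102,0.0002425622,0.0163629,0.0004985298
103,0.0002349493,0.01632532,0.0004896777
104,0.0002276456,0.016288,0.0004810667
105,0.0002206355,0.01625091,0.000472688
106,0.0002139047,0.01621407,0.0004645335
107,0.0002074396,0.01617747,0.0004565953
108,0.0002012274,0.0161411,0.0004488659
109,0.0001952558,0.01610497,0.0004413381
110,0.0001895137,0.01606907,0.000434005
111,0.00018399,0.0160334,0.0004268599
112,0.0001786748,0.01599795,0.0004198967
113,0.0001735584,0.01596273,0.0004131091
114,0.0001686316,0.01592774,0.0004064915
115,0.0001638859,0.01589296,0.0004000381
116,0.0001593131,0.0158584,0.0003937438
117,0.0001549055,0.01582406,0.0003876033
118,0.0001506558,0.01578993,0.0003816118
119,0.0001465572,0.01575601,0.0003757644
120,0.0001426029,0.0157223,0.0003700567
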