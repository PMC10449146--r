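# name: aluminium
# density_g_cm3: 2.699
# z_eff: 13.0000
energy_keV,mu_pe_per_mm,mu_compton_per_mm,mu_rayleigh_per_mm
16,1.80459,0.04907955,0.06735933
17,1.480206,0.04890605,0.06187314
18,1.227966,0.04873418,0.05704912
19,1.029054,0.0485639,0.05278264
20,0.870217,0.04839521,0.04898915
21,0.7419424,0.04822806,0.04559972
22,0.6372873,0.04806246,0.04255767
23,0.5511074,0.04789836,0.0398161
24,0.4795381,0.04773576,0.03733586
25,0.4196397,0.04757463,0.03508409
26,0.3691501,0.04741495,0.03303304
27,0.3263103,0.0472567,0.0311591
28,0.2897391,0.04709987,0.0294421
29,0.2583421,0.04694443,0.02786471
30,0.2312449,0.04679037,0.02641197
31,0.2077433,0.04663767,0.02507091
32,0.1872665,0.0464863,0.02383021
33,0.1693479,0.04633626,0.02268001
34,0.1536044,0.04618753,0.0216116
35,0.1397192,0.04604008,0.02061734
36,0.1274288,0.0458939,0.01969048
37,0.1165132,0.04574898,0.01882499
38,0.1067873,0.0456053,0.01801555
39,0.09809514,0.04546284,0.01725739
40,0.09030442,0.04532159,0.01654624
41,0.08330249,0.04518153,0.01587827
42,0.07699307,0.04504264,0.01525005
43,0.07129355,0.04490492,0.01465847
44,0.06613277,0.04476835,0.01410073
45,0.06144926,0.0446329,0.01357428
46,0.05718968,0.04449858,0.01307683
47,0.05330768,0.04436536,0.01260627
48,0.04976277,0.04423323,0.01216071
49,0.04651956,0.04410218,0.0117384
50,0.04354697,0.04397219,0.01133774
51,0.04081767,0.04384325,0.01095728
52,0.03830755,0.04371535,0.01059569
53,0.03599528,0.04358848,0.01025174
54,0.03386197,0.04346262,0.009924297
55,0.03189082,0.04333776,0.009612322
56,0.03006689,0.04321389,0.009314857
57,0.02837684,0.04309099,0.009031017
58,0.02680875,0.04296906,0.008759983
59,0.02535194,0.04284809,0.008500997
60,0.02399681,0.04272805,0.008253355
61,0.02273476,0.04260895,0.008016406
62,0.021558,0.04249077,0.007789543
63,0.02045955,0.04237349,0.007572204
64,0.01943307,0.04225712,0.007363862
65,0.01847283,0.04214163,0.00716403
66,0.01757362,0.04202702,0.006972251
67,0.01673074,0.04191327,0.006788099
68,0.01593988,0.04180039,0.006611175
69,0.01519715,0.04168835,0.006441107
70,0.01449898,0.04157714,0.006277547
71,0.01384212,0.04146677,0.006120166
72,0.01322358,0.04135722,0.00596866
73,0.01264065,0.04124847,0.005822739
74,0.01209084,0.04114053,0.005682134
75,0.01157184,0.04103337,0.005546589
76,0.01108156,0.040927,0.005415867
77,0.01061806,0.0408214,0.005289741
78,0.01017956,0.04071656,0.005167999
79,0.009764409,0.04061249,0.005050441
80,0.009371097,0.04050916,0.004936879
81,0.008998223,0.04040657,0.004827134
82,0.008644491,0.04030471,0.004721037
83,0.008308703,0.04020357,0.004618429
84,0.007989748,0.04010315,0.004519159
85,0.007686597,0.04000343,0.004423086
86,0.007398295,0.03990442,0.004330073
87,0.007123955,0.0398061,0.004239992
88,0.00686275,0.03970846,0.004152723
89,0.006613914,0.0396115,0.004068149
90,0.006376731,0.03951521,0.003986162
91,0.006150535,0.03941959,0.003906658
92,0.005934705,0.03932462,0.003829538
93,0.005728661,0.0392303,0.003754707
94,0.00553186,0.03913662,0.003682077
95,0.005343797,0.03904357,0.003611563
96,0.005163997,0.03895116,0.003543083
97,0.004992017,0.03885936,0.003476561
98,0.004827442,0.03876818,0.003411923
99,0.004669881,0.03867761,0.0033491
100,0.00451897,0.03858764,0.003288023
101,0.004374365,0.03849827,0.003228629
102,0.004235744,0.03840949,0.003170858
103,0.004102805,0.0383213,0.003114651
104,0.003975263,0.03823368,0.003059953
105,0.00385285,0.03814663,0.00300671
106,0.003735313,0.03806015,0.002954871
107,0.003622416,0.03797423,0.002904389
108,0.003513934,0.03788887,0.002855215
109,0.003409657,0.03780405,0.002807307
110,0.003309384,0.03771978,0.00276062
111,0.003212928,0.03763604,0.002715114
112,0.003120111,0.03755284,0.00267075
113,0.003030764,0.03747017,0.00262749
114,0.00294473,0.03738802,0.002585298
115,0.002861858,0.03730639,0.00254414
116,0.002782006,0.03722526,0.002503982
117,0.002705039,0.03714465,0.002464792
118,0.002630829,0.03706454,0.00242654
119,0.002559256,0.03698492,0.002389196
120,0.002490204,0.0369058,0.002352732
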