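# name: bone
# density_g_cm3: 1.92
# z_eff: 13.2281
energy_keV,mu_pe_per_mm,mu_compton_per_mm,mu_rayleigh_per_mm
16,1.807586,0.03730416,0.04129741
17,1.482664,0.03717229,0.03794976
18,1.230004,0.03704165,0.03500436
19,1.030762,0.03691223,0.03239802
20,0.8716617,0.03678401,0.03007956
21,0.7431742,0.03665697,0.02800723
22,0.6383454,0.03653109,0.02614664
23,0.5520224,0.03640637,0.02446931
24,0.4803342,0.03628278,0.02295144
25,0.4203363,0.0361603,0.02157304
26,0.3697629,0.03603894,0.0203172
27,0.326852,0.03591866,0.01916955
28,0.2902201,0.03579945,0.01811778
29,0.258771,0.03568131,0.01715134
30,0.2316288,0.03556421,0.01626109
31,0.2080882,0.03544814,0.01543911
32,0.1875774,0.0353331,0.01467849
33,0.1696291,0.03521905,0.01397321
34,0.1538594,0.035106,0.01331796
35,0.1399512,0.03499393,0.01270807
36,0.1276404,0.03488283,0.01213939
37,0.1167066,0.03477268,0.01160827
38,0.1069646,0.03466347,0.01111145
39,0.098258,0.03455519,0.010646
40,0.09045434,0.03444783,0.01020933
41,0.08344079,0.03434137,0.009799092
42,0.07712089,0.03423581,0.009413186
43,0.07141191,0.03413113,0.009049715
44,0.06624257,0.03402732,0.008706965
45,0.06155127,0.03392437,0.008383383
46,0.05728463,0.03382228,0.008077563
47,0.05339618,0.03372102,0.007788222
48,0.04984539,0.03362059,0.007514196
49,0.04659679,0.03352098,0.007254418
50,0.04361927,0.03342218,0.007007917
51,0.04088544,0.03332418,0.006773801
52,0.03837115,0.03322697,0.006551253
53,0.03605504,0.03313053,0.006339522
54,0.03391819,0.03303487,0.006137919
55,0.03194377,0.03293997,0.005945806
56,0.03011681,0.03284582,0.005762597
57,0.02842395,0.03275241,0.005587751
58,0.02685326,0.03265973,0.005420765
59,0.02539403,0.03256778,0.005261176
60,0.02403665,0.03247654,0.005108554
61,0.0227725,0.03238602,0.004962499
62,0.0215938,0.03229619,0.00482264
63,0.02049352,0.03220705,0.004688631
64,0.01946534,0.03211859,0.004560152
65,0.0185035,0.03203081,0.004436903
66,0.0176028,0.0319437,0.004318604
67,0.01675851,0.03185725,0.004204993
68,0.01596635,0.03177145,0.004095828
69,0.01522238,0.03168629,0.003990878
70,0.01452305,0.03160177,0.003889931
71,0.0138651,0.03151787,0.003792786
72,0.01324554,0.0314346,0.003699255
73,0.01266164,0.03135195,0.003609161
74,0.01211091,0.0312699,0.003522338
75,0.01159105,0.03118846,0.00343863
76,0.01109996,0.03110761,0.003357891
77,0.01063569,0.03102734,0.003279982
78,0.01019646,0.03094766,0.003204772
79,0.00978062,0.03086855,0.003132139
80,0.009386655,0.03079001,0.003061967
81,0.009013162,0.03071204,0.002994146
82,0.008658842,0.03063462,0.002928573
83,0.008322497,0.03055775,0.00286515
84,0.008003012,0.03048142,0.002803783
85,0.007699359,0.03040563,0.002744387
86,0.007410578,0.03033037,0.002686877
87,0.007135782,0.03025564,0.002631174
88,0.006874143,0.03018143,0.002577205
89,0.006624894,0.03010773,0.002524898
90,0.006387317,0.03003454,0.002474186
91,0.006160746,0.02996186,0.002425005
92,0.005944558,0.02988968,0.002377294
93,0.005738172,0.02981798,0.002330996
94,0.005541044,0.02974678,0.002286055
95,0.005352669,0.02967606,0.00224242
96,0.005172571,0.02960582,0.00220004
97,0.005000305,0.02953605,0.002158868
98,0.004835456,0.02946674,0.002118859
99,0.004677634,0.0293979,0.00207997
100,0.004526472,0.02932952,0.002042159
101,0.004381627,0.02926159,0.002005387
102,0.004242776,0.02919411,0.001969617
103,0.004109616,0.02912707,0.001934812
104,0.003981862,0.02906048,0.001900939
105,0.003859246,0.02899432,0.001867965
106,0.003741515,0.02892858,0.001835858
107,0.00362843,0.02886328,0.001804589
108,0.003519768,0.0287984,0.001774129
109,0.003415317,0.02873393,0.00174445
110,0.003314878,0.02866988,0.001715525
111,0.003218262,0.02860623,0.001687331
112,0.003125291,0.02854299,0.001659842
113,0.003035796,0.02848016,0.001633035
114,0.002949619,0.02841771,0.001606889
115,0.002866609,0.02835567,0.001581381
116,0.002786625,0.02829401,0.001556492
117,0.00270953,0.02823274,0.001532201
118,0.002635197,0.02817184,0.00150849
119,0.002563505,0.02811133,0.00148534
120,0.002494339,0.02805119,0.001462734
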