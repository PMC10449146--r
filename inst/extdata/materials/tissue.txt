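# name: tissue
# density_g_cm3: 1.06
# z_eff: 7.2044
energy_keV,mu_pe_per_mm,mu_compton_per_mm,mu_rayleigh_per_mm
16,0.1044884,0.02206125,0.01111165
17,0.08570611,0.02198326,0.01017141
18,0.07110101,0.021906,0.009348236
19,0.05958372,0.02182946,0.008623073
20,0.05038684,0.02175363,0.007980639
21,0.04295955,0.0216785,0.007408569
22,0.03689987,0.02160406,0.006896758
23,0.03190992,0.0215303,0.006436885
24,0.02776596,0.02145721,0.006022038
25,0.02429775,0.02138478,0.005646439
26,0.02137433,0.02131301,0.005305221
27,0.01889384,0.02124188,0.004994259
28,0.01677632,0.02117138,0.004710041
29,0.01495838,0.02110151,0.004449553
30,0.01338942,0.02103226,0.004210203
31,0.01202864,0.02096362,0.003989746
32,0.010843,0.02089558,0.00378623
33,0.009805491,0.02082814,0.003597953
34,0.00889392,0.02076128,0.003423422
35,0.008089945,0.020695,0.003261324
36,0.007378315,0.0206293,0.003110502
37,0.006746282,0.02056416,0.00296993
38,0.00618314,0.02049957,0.002838696
39,0.005679852,0.02043554,0.002715991
40,0.005228758,0.02037204,0.002601088
41,0.004823336,0.02030909,0.00249334
42,0.004458011,0.02024666,0.002392164
43,0.004128001,0.02018475,0.002297035
44,0.003829184,0.02012336,0.002207481
45,0.003558002,0.02006248,0.002123074
46,0.003311366,0.0200021,0.002043428
47,0.003086592,0.01994222,0.00196819
48,0.002881337,0.01988283,0.001897043
49,0.002693551,0.01982392,0.001829694
50,0.002521433,0.01976549,0.001765878
51,0.002363403,0.01970753,0.001705353
52,0.002218063,0.01965004,0.001647896
53,0.002084179,0.01959301,0.001593305
54,0.001960657,0.01953644,0.001541391
55,0.001846525,0.01948031,0.001491983
56,0.001740917,0.01942463,0.001444922
57,0.001643061,0.01936939,0.001400062
58,0.001552266,0.01931458,0.001357269
59,0.001467914,0.01926021,0.001316418
60,0.00138945,0.01920625,0.001277393
61,0.001316376,0.01915271,0.001240088
62,0.00124824,0.01909959,0.001204403
63,0.001184638,0.01904687,0.001170245
64,0.001125203,0.01899456,0.00113753
65,0.001069604,0.01894265,0.001106177
66,0.001017538,0.01889113,0.001076112
67,0.0009687342,0.01884001,0.001047266
68,0.0009229426,0.01878926,0.001019574
69,0.0008799374,0.0187389,0.0009929751
70,0.0008395122,0.01868892,0.0009674132
71,0.0008014788,0.0186393,0.0009428352
72,0.0007656647,0.01859006,0.0009191914
73,0.0007319124,0.01854118,0.0008964352
74,0.0007000772,0.01849266,0.0008745231
75,0.0006700266,0.01844449,0.0008534139
76,0.0006416386,0.01839668,0.0008330692
77,0.0006148013,0.01834921,0.0008134525
78,0.0005894113,0.01830209,0.0007945297
79,0.0005653735,0.0182553,0.0007762687
80,0.0005426002,0.01820886,0.0007586391
81,0.0005210103,0.01816274,0.0007416123
82,0.0005005287,0.01811696,0.0007251612
83,0.000481086,0.01807149,0.0007092604
84,0.0004626181,0.01802636,0.0006938857
85,0.0004450652,0.01798153,0.0006790142
86,0.0004283721,0.01793703,0.0006646245
87,0.0004124874,0.01789283,0.000650696
88,0.0003973633,0.01784894,0.0006372093
89,0.0003829553,0.01780536,0.0006241461
90,0.000369222,0.01776208,0.0006114889
91,0.000356125,0.0177191,0.0005992212
92,0.0003436281,0.01767641,0.0005873272
93,0.0003316978,0.01763401,0.0005757921
94,0.0003203028,0.0175919,0.0005646017
95,0.0003094137,0.01755008,0.0005537424
96,0.000299003,0.01750853,0.0005432014
97,0.0002890451,0.01746727,0.0005329664
98,0.0002795159,0.01742629,0.0005230259
99,0.0002703929,0.01738558,0.0005133687
100,0.0002616549,0.01734514,0.0005039842
101,0.0002532821,0.01730496,0.0004948623
102,0.0002452558,0.01726506,0.0004859934
103,0.0002375584,0.01722541,0.0004773684
104,0.0002301735,0.01718603,0.0004689783
105,0.0002230856,0.0171469,0.0004608149
106,0.0002162801,0.01710803,0.00045287
107,0.0002097432,0.01706941,0.0004451361
108,0.0002034619,0.01703104,0.0004376057
109,0.0001974241,0.01699291,0.000430272
110,0.0001916182,0.01695503,0.000423128
111,0.0001860332,0.01691739,0.0004161675
112,0.000180659,0.01687999,0.0004093842
113,0.0001754857,0.01684283,0.0004027722
114,0.0001705042,0.01680591,0.0003963258
115,0.0001657058,0.01676921,0.0003900397
116,0.0001610822,0.01673275,0.0003839086
117,0.0001566257,0.01669651,0.0003779274
118,0.0001523288,0.0166605,0.0003720915
119,0.0001481846,0.01662471,0.0003663961
120,0.0001441865,0.01658915,0.0003608369
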