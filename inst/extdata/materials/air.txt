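# name: air
# density_g_cm3: 0.001205
# z_eff: 7.6253
energy_keV,mu_pe_per_mm,mu_compton_per_mm,mu_rayleigh_per_mm
16,0.0001294388,2.270264e-05,1.357541e-05
17,0.0001061715,2.262238e-05,1.242677e-05
18,8.807893e-05,2.254288e-05,1.142112e-05
19,7.381148e-05,2.246412e-05,1.053517e-05
20,6.24185e-05,2.238608e-05,9.750276e-06
21,5.321769e-05,2.230877e-05,9.051327e-06
22,4.571104e-05,2.223216e-05,8.425988e-06
23,3.952957e-05,2.215626e-05,7.864096e-06
24,3.439608e-05,2.208104e-05,7.357212e-06
25,3.009971e-05,2.200651e-05,6.898276e-06
26,2.647822e-05,2.193264e-05,6.481346e-06
27,2.340543e-05,2.185944e-05,6.101383e-06
28,2.078227e-05,2.17869e-05,5.754096e-06
29,1.853024e-05,2.1715e-05,5.435806e-06
30,1.658662e-05,2.164373e-05,5.143344e-06
31,1.490091e-05,2.15731e-05,4.873967e-06
32,1.343216e-05,2.150308e-05,4.625292e-06
33,1.21469e-05,2.143368e-05,4.395238e-06
34,1.101766e-05,2.136488e-05,4.181981e-06
35,1.002171e-05,2.129667e-05,3.983918e-06
36,9.140153e-06,2.122906e-05,3.799634e-06
37,8.357199e-06,2.116202e-05,3.627874e-06
38,7.659587e-06,2.109556e-05,3.467527e-06
39,7.036121e-06,2.102966e-05,3.317601e-06
40,6.477312e-06,2.096432e-05,3.17721e-06
41,5.975081e-06,2.089953e-05,3.045561e-06
42,5.522522e-06,2.083529e-05,2.921943e-06
43,5.113709e-06,2.077159e-05,2.805714e-06
44,4.74354e-06,2.070841e-05,2.696298e-06
45,4.407603e-06,2.064576e-05,2.593171e-06
46,4.102074e-06,2.058362e-05,2.495861e-06
47,3.823627e-06,2.0522e-05,2.403939e-06
48,3.56936e-06,2.046088e-05,2.317014e-06
49,3.336733e-06,2.040026e-05,2.234731e-06
50,3.123516e-06,2.034013e-05,2.156765e-06
51,2.92775e-06,2.028049e-05,2.082819e-06
52,2.747706e-06,2.022133e-05,2.012624e-06
53,2.581852e-06,2.016264e-05,1.945928e-06
54,2.428835e-06,2.010442e-05,1.882505e-06
55,2.287449e-06,2.004667e-05,1.822143e-06
56,2.156623e-06,1.998937e-05,1.764649e-06
57,2.035401e-06,1.993252e-05,1.709845e-06
58,1.922925e-06,1.987612e-05,1.657566e-06
59,1.818432e-06,1.982016e-05,1.607659e-06
60,1.721232e-06,1.976464e-05,1.559984e-06
61,1.630708e-06,1.970954e-05,1.51441e-06
62,1.546302e-06,1.965487e-05,1.470814e-06
63,1.467513e-06,1.960063e-05,1.429086e-06
64,1.393886e-06,1.95468e-05,1.38912e-06
65,1.32501e-06,1.949337e-05,1.350818e-06
66,1.260512e-06,1.944036e-05,1.31409e-06
67,1.200054e-06,1.938774e-05,1.278851e-06
68,1.143328e-06,1.933553e-05,1.245022e-06
69,1.090054e-06,1.92837e-05,1.212529e-06
70,1.039976e-06,1.923226e-05,1.181302e-06
71,9.928606e-07,1.918121e-05,1.151278e-06
72,9.484947e-07,1.913053e-05,1.122394e-06
73,9.066828e-07,1.908023e-05,1.094596e-06
74,8.672458e-07,1.90303e-05,1.067828e-06
75,8.300195e-07,1.898073e-05,1.042042e-06
76,7.948529e-07,1.893153e-05,1.017189e-06
77,7.616072e-07,1.888268e-05,9.932256e-07
78,7.301544e-07,1.883419e-05,9.701101e-07
79,7.003768e-07,1.878604e-05,9.47803e-07
80,6.721655e-07,1.873825e-05,9.262674e-07
81,6.454202e-07,1.869079e-05,9.054681e-07
82,6.200479e-07,1.864367e-05,8.853722e-07
83,5.959626e-07,1.859689e-05,8.659485e-07
84,5.730848e-07,1.855044e-05,8.471675e-07
85,5.513405e-07,1.850431e-05,8.290013e-07
86,5.306614e-07,1.845851e-05,8.114236e-07
87,5.109836e-07,1.841303e-05,7.944093e-07
88,4.92248e-07,1.836787e-05,7.779347e-07
89,4.743996e-07,1.832302e-05,7.619775e-07
90,4.573871e-07,1.827848e-05,7.465163e-07
91,4.411626e-07,1.823425e-05,7.315308e-07
92,4.256817e-07,1.819032e-05,7.17002e-07
93,4.109026e-07,1.814668e-05,7.029115e-07
94,3.967866e-07,1.810335e-05,6.89242e-07
95,3.832973e-07,1.806031e-05,6.75977e-07
96,3.704007e-07,1.801756e-05,6.631008e-07
97,3.58065e-07,1.79751e-05,6.505985e-07
98,3.462604e-07,1.793293e-05,6.384558e-07
99,3.34959e-07,1.789103e-05,6.266592e-07
100,3.241345e-07,1.784941e-05,6.151958e-07
101,3.137623e-07,1.780807e-05,6.040532e-07
102,3.038194e-07,1.776701e-05,5.932196e-07
103,2.94284e-07,1.772621e-05,5.826838e-07
104,2.851357e-07,1.768568e-05,5.72435e-07
105,2.763553e-07,1.764542e-05,5.624631e-07
106,2.679247e-07,1.760541e-05,5.527582e-07
107,2.598269e-07,1.756567e-05,5.433109e-07
108,2.520458e-07,1.752618e-05,5.341123e-07
109,2.445662e-07,1.748695e-05,5.251538e-07
110,2.373739e-07,1.744797e-05,5.164272e-07
111,2.304553e-07,1.740923e-05,5.079246e-07
112,2.237978e-07,1.737075e-05,4.996385e-07
113,2.173892e-07,1.733251e-05,4.915617e-07
114,2.112182e-07,1.729451e-05,4.836872e-07
115,2.05274e-07,1.725675e-05,4.760083e-07
116,1.995464e-07,1.721922e-05,4.685188e-07
117,1.940257e-07,1.718193e-05,4.612125e-07
118,1.887028e-07,1.714487e-05,4.540836e-07
119,1.835691e-07,1.710805e-05,4.471263e-07
120,1.786162e-07,1.707145e-05,4.403353e-07
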