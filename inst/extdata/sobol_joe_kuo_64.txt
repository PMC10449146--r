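# Joe-Kuo Sobol' direction numbers (new-joe-kuo-6), first 64 dimensions.
# Columns: dimension index (1-based), primitive polynomial (encoded as integer,
# leading and trailing bits included), then initial direction integers m_1..m_18
# (zero-padded beyond the polynomial degree). Public domain data of S. Joe and F. Y. Kuo.
1 1 1 0 0 0 0 0 0 0 0 0 0 0 0 0 0 0 0 0
2 3 1 0 0 0 0 0 0 0 0 0 0 0 0 0 0 0 0 0
3 7 1 3 0 0 0 0 0 0 0 0 0 0 0 0 0 0 0 0
4 11 1 3 1 0 0 0 0 0 0 0 0 0 0 0 0 0 0 0
5 13 1 1 1 0 0 0 0 0 0 0 0 0 0 0 0 0 0 0
6 19 1 1 3 3 0 0 0 0 0 0 0 0 0 0 0 0 0 0
7 25 1 3 5 13 0 0 0 0 0 0 0 0 0 0 0 0 0 0
8 37 1 1 5 5 17 0 0 0 0 0 0 0 0 0 0 0 0 0
9 41 1 1 5 5 5 0 0 0 0 0 0 0 0 0 0 0 0 0
10 47 1 1 7 11 19 0 0 0 0 0 0 0 0 0 0 0 0 0
11 55 1 1 5 1 1 0 0 0 0 0 0 0 0 0 0 0 0 0
12 59 1 1 1 3 11 0 0 0 0 0 0 0 0 0 0 0 0 0
13 61 1 3 5 5 31 0 0 0 0 0 0 0 0 0 0 0 0 0
14 67 1 3 3 9 7 49 0 0 0 0 0 0 0 0 0 0 0 0
15 91 1 1 1 15 21 21 0 0 0 0 0 0 0 0 0 0 0 0
16 97 1 3 1 13 27 49 0 0 0 0 0 0 0 0 0 0 0 0
17 103 1 1 1 15 7 5 0 0 0 0 0 0 0 0 0 0 0 0
18 109 1 3 1 15 13 25 0 0 0 0 0 0 0 0 0 0 0 0
19 115 1 1 5 5 19 61 0 0 0 0 0 0 0 0 0 0 0 0
20 131 1 3 7 11 23 15 103 0 0 0 0 0 0 0 0 0 0 0
21 137 1 3 7 13 13 15 69 0 0 0 0 0 0 0 0 0 0 0
22 143 1 1 3 13 7 35 63 0 0 0 0 0 0 0 0 0 0 0
23 145 1 3 5 9 1 25 53 0 0 0 0 0 0 0 0 0 0 0
24 157 1 3 1 13 9 35 107 0 0 0 0 0 0 0 0 0 0 0
25 167 1 3 1 5 27 61 31 0 0 0 0 0 0 0 0 0 0 0
26 171 1 1 5 11 19 41 61 0 0 0 0 0 0 0 0 0 0 0
27 185 1 3 5 3 3 13 69 0 0 0 0 0 0 0 0 0 0 0
28 191 1 1 7 13 1 19 1 0 0 0 0 0 0 0 0 0 0 0
29 193 1 3 7 5 13 19 59 0 0 0 0 0 0 0 0 0 0 0
30 203 1 1 3 9 25 29 41 0 0 0 0 0 0 0 0 0 0 0
31 211 1 3 5 13 23 1 55 0 0 0 0 0 0 0 0 0 0 0
32 213 1 3 7 3 13 59 17 0 0 0 0 0 0 0 0 0 0 0
33 229 1 3 1 3 5 53 69 0 0 0 0 0 0 0 0 0 0 0
34 239 1 1 5 5 23 33 13 0 0 0 0 0 0 0 0 0 0 0
35 241 1 1 7 7 1 61 123 0 0 0 0 0 0 0 0 0 0 0
36 247 1 1 7 9 13 61 49 0 0 0 0 0 0 0 0 0 0 0
37 253 1 3 3 5 3 55 33 0 0 0 0 0 0 0 0 0 0 0
38 285 1 3 1 15 31 13 49 245 0 0 0 0 0 0 0 0 0 0
39 299 1 3 5 15 31 59 63 97 0 0 0 0 0 0 0 0 0 0
40 301 1 3 1 11 11 11 77 249 0 0 0 0 0 0 0 0 0 0
41 333 1 3 1 11 27 43 71 9 0 0 0 0 0 0 0 0 0 0
42 351 1 1 7 15 21 11 81 45 0 0 0 0 0 0 0 0 0 0
43 355 1 3 7 3 25 31 65 79 0 0 0 0 0 0 0 0 0 0
44 357 1 3 1 1 19 11 3 205 0 0 0 0 0 0 0 0 0 0
45 361 1 1 5 9 19 21 29 157 0 0 0 0 0 0 0 0 0 0
46 369 1 3 7 11 1 33 89 185 0 0 0 0 0 0 0 0 0 0
47 391 1 3 3 3 15 9 79 71 0 0 0 0 0 0 0 0 0 0
48 397 1 3 7 11 15 39 119 27 0 0 0 0 0 0 0 0 0 0
49 425 1 1 3 1 11 31 97 225 0 0 0 0 0 0 0 0 0 0
50 451 1 1 1 3 23 43 57 177 0 0 0 0 0 0 0 0 0 0
51 463 1 3 7 7 17 17 37 71 0 0 0 0 0 0 0 0 0 0
52 487 1 3 1 5 27 63 123 213 0 0 0 0 0 0 0 0 0 0
53 501 1 1 3 5 11 43 53 133 0 0 0 0 0 0 0 0 0 0
54 529 1 3 5 5 29 17 47 173 479 0 0 0 0 0 0 0 0 0
55 539 1 3 3 11 3 1 109 9 69 0 0 0 0 0 0 0 0 0
56 545 1 1 1 5 17 39 23 5 343 0 0 0 0 0 0 0 0 0
57 557 1 3 1 5 25 15 31 103 499 0 0 0 0 0 0 0 0 0
58 563 1 1 1 11 11 17 63 105 183 0 0 0 0 0 0 0 0 0
59 601 1 1 5 11 9 29 97 231 363 0 0 0 0 0 0 0 0 0
60 607 1 1 5 15 19 45 41 7 383 0 0 0 0 0 0 0 0 0
61 617 1 3 7 7 31 19 83 137 221 0 0 0 0 0 0 0 0 0
62 623 1 1 1 3 23 15 111 223 83 0 0 0 0 0 0 0 0 0
63 631 1 1 5 13 31 15 55 25 161 0 0 0 0 0 0 0 0 0
64 637 1 1 3 13 25 47 39 87 257 0 0 0 0 0 0 0 0 0
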