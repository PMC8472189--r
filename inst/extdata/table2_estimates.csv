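congener,phyto_est,phyto_obs,phyto_rel_err,phyto_test_set,estro_est,estro_obs,estro_rel_err,estro_test_set
0,80.694,,,,71.424,,,
1,80.325,75.426,-6.50,0,70.958,,,
2,84.363,81.624,-3.36,0,70.674,69.396,-1.84,0
3,83.949,82.426,-1.85,0,67.889,65.720,-3.30,1
4,73.802,73.822,0.03,0,63.977,63.512,-0.73,0
5,79.090,80.007,1.15,0,71.672,,,
6,83.632,83.766,0.16,0,71.588,,,
7,83.259,83.786,0.63,0,67.399,,,
8,85.749,87.006,1.44,1,68.852,,,
9,78.359,80.980,3.24,1,72.131,,,
10,71.729,72.398,0.92,0,64.205,,,
11,83.118,87.533,5.04,0,73.814,73.504,-0.42,0
12,88.281,88.323,0.05,0,67.752,,,
13,89.938,88.073,-2.12,0,67.219,67.002,-0.32,0
14,81.876,,,,72.630,,,
15,89.550,86.282,-3.79,0,65.043,,,
16,75.274,69.318,-8.59,0,64.841,,,
17,72.967,,,,60.820,,,
18,72.089,71.252,-1.17,0,63.389,,,
19,69.084,,,,56.327,,,
20,82.354,79.668,-3.37,0,72.228,70.152,-2.96,0
21,82.154,,,,68.549,,,
22,84.490,,,,69.539,,,
23,76.212,82.007,7.07,0,72.676,,,
24,63.846,,,,64.834,69.621,6.88,0
25,86.493,89.403,3.25,0,67.989,,,
26,81.368,,,,72.709,,,
27,74.870,,,,64.884,,,
28,88.612,89.893,1.42,1,65.302,,,
29,80.237,,,,67.876,,,
30,70.770,,,,60.778,56.932,-6.76,0
31,83.420,86.392,3.44,0,70.012,,,
32,65.574,,,,61.050,,,
33,89.357,90.196,0.93,0,68.142,67.742,-0.59,0
34,87.497,,,,71.727,,,
35,86.138,,,,69.104,,,
36,91.986,91.012,-1.07,0,73.519,,,
37,91.435,,,,64.331,,,
38,92.285,,,,69.477,66.772,-4.05,0
39,91.511,90.431,-1.19,0,69.204,,,
40,73.327,73.154,-0.24,0,65.302,,,
41,68.109,,,,61.187,,,
42,74.542,,,,61.114,,,
43,74.076,,,,64.081,,,
44,66.061,,,,65.927,,,
45,60.125,,,,56.469,,,
46,66.153,65.282,-1.33,0,54.948,,,
47,65.818,,,,57.198,60.010,4.69,0
48,65.849,,,,60.330,,,
49,71.324,,,,61.956,65.967,6.08,1
50,68.467,,,,53.531,51.652,-3.64,0
51,63.434,,,,52.778,,,
52,67.203,67.751,0.81,0,64.519,,,
53,68.356,,,,66.008,,,
54,66.777,,,,60.121,,,
55,85.426,,,,69.076,,,
56,88.107,,,,68.780,,,
57,79.168,,,,73.179,75.837,3.51,0
58,86.389,,,,72.286,,,
59,66.140,,,,65.444,,,
60,87.500,,,,66.423,67.218,1.18,0
61,78.246,,,,68.885,,,
62,65.854,,,,60.866,,,
63,81.240,,,,70.529,,,
64,64.290,,,,57.249,,,
65,60.271,,,,62.106,64.739,4.07,0
66,92.187,,,,64.582,70.824,8.81,1
67,83.173,,,,68.420,,,
68,90.326,,,,68.134,,,
69,74.005,,,,61.429,,,
70,86.766,,,,69.266,68.144,-1.65,0
71,68.635,,,,61.179,58.979,-3.73,0
72,84.899,,,,72.836,77.695,6.25,0
73,73.877,,,,64.293,,,
74,85.224,85.467,0.28,0,65.771,,,
75,64.592,,,,57.676,,,
76,91.184,,,,68.336,,,
77,97.273,99.318,2.06,0,64.961,,,
78,95.861,,,,70.370,,,
79,88.812,,,,69.859,,,
80,88.972,83.873,-6.08,0,74.719,,,
81,95.415,99.705,4.30,1,66.087,70.222,5.89,0
82,75.659,83.729,9.64,0,61.660,64.109,3.82,0
83,75.123,,,,64.490,,,
84,60.484,,,,58.008,,,
85,67.346,64.546,-4.34,0,57.494,,,
86,67.811,,,,60.494,,,
87,68.117,,,,62.251,,,
88,60.852,,,,53.986,,,
89,61.130,,,,52.143,,,
90,73.421,,,,60.341,,,
91,62.968,,,,53.689,,,
92,64.058,,,,65.180,,,
93,62.641,,,,55.883,,,
94,71.336,,,,55.614,,,
95,65.125,70.561,7.70,1,58.455,,,
96,79.861,,,,66.412,,,
97,76.133,,,,61.494,59.222,-3.84,0
98,65.547,,,,51.651,52.414,1.46,0
99,65.061,,,,56.699,,,
100,62.776,,,,50.011,,,
101,72.904,71.570,-1.86,0,61.497,65.198,5.68,1
102,68.287,,,,53.276,,,
103,73.465,,,,54.758,,,
104,69.305,,,,62.315,,,
105,91.091,,,,65.655,,,
106,81.145,,,,69.353,,,
107,84.562,,,,70.567,,,
108,89.361,,,,69.117,,,
109,67.583,,,,57.749,,,
110,68.633,71.019,3.36,1,61.736,60.469,-2.10,0
111,82.886,,,,73.235,68.404,-7.06,0
112,63.621,,,,62.042,62.049,0.01,1
113,70.030,,,,64.786,,,
114,83.185,,,,66.746,,,
115,58.217,,,,55.372,,,
116,61.924,,,,58.568,,,
117,67.104,,,,57.672,57.287,-0.67,0
118,88.524,85.897,-3.06,0,65.011,,,
119,67.740,,,,57.761,,,
120,86.663,,,,68.555,,,
121,71.060,,,,55.813,,,
122,90.103,,,,68.870,68.399,-0.69,0
123,93.991,95.620,1.70,0,64.795,,,
124,88.268,,,,69.449,,,
125,75.464,,,,60.670,,,
126,99.156,105.165,5.71,0,66.748,,,
127,92.611,,,,71.565,,,
128,68.328,66.586,-2.62,0,58.372,59.488,1.88,0
129,71.759,,,,62.271,,,
130,74.548,72.689,-2.56,0,62.574,59.408,-5.33,1
131,62.701,,,,52.006,,,
132,66.789,,,,54.858,,,
133,73.554,,,,65.404,,,
134,62.993,,,,56.028,,,
135,64.861,,,,59.012,,,
136,64.381,,,,50.250,,,
137,67.115,,,,58.501,,,
138,68.889,69.900,1.45,0,57.865,,,
139,68.238,,,,50.422,,,
140,60.491,,,,48.887,,,
141,74.464,,,,61.583,,,
142,70.237,,,,52.663,,,
143,66.244,,,,54.364,,,
144,64.648,,,,55.168,,,
145,74.108,,,,61.477,63.476,3.15,1
146,75.031,,,,60.764,,,
147,65.471,,,,52.282,,,
148,70.797,,,,52.261,,,
149,68.510,,,,54.156,54.240,0.16,0
150,79.539,,,,46.136,,,
151,67.629,,,,57.030,56.600,-0.76,0
152,77.851,,,,63.524,,,
153,66.585,67.731,1.69,0,57.174,,,
154,67.694,,,,50.534,,,
155,74.516,,,,64.116,,,
156,86.505,89.360,3.19,0,66.754,,,
157,93.025,,,,65.739,,,
158,69.996,,,,60.483,55.534,-8.91,1
159,84.798,82.536,-2.74,0,69.399,,,
160,65.245,,,,58.509,,,
161,71.927,,,,56.126,57.228,1.93,0
162,86.262,,,,69.840,,,
163,66.042,,,,64.367,,,
164,73.207,73.038,-0.23,0,59.661,,,
165,66.114,,,,62.462,,,
166,60.991,,,,54.165,,,
167,90.001,89.597,-0.45,0,65.217,,,
168,77.170,,,,57.249,,,
169,95.088,,,,67.929,69.672,2.50,0
170,73.365,72.234,-1.57,0,58.643,,,
171,70.282,,,,49.261,,,
172,69.300,,,,61.413,,,
173,70.549,,,,53.322,55.317,3.61,0
174,70.357,67.737,-3.87,0,55.179,,,
175,82.557,,,,56.668,,,
176,71.336,72.986,2.26,0,63.146,,,
177,66.333,67.823,2.20,1,52.939,50.357,-5.13,0
178,67.363,,,,57.564,,,
179,66.274,,,,48.973,,,
180,68.687,72.489,5.24,0,57.952,55.123,-5.13,0
181,73.058,,,,49.108,,,
182,65.665,,,,51.597,,,
183,71.546,71.487,-0.08,0,50.906,52.807,3.60,1
184,73.752,,,,43.131,,,
185,75.222,,,,53.835,,,
186,73.291,75.368,2.76,0,58.614,,,
187,71.067,,,,52.759,,,
188,77.819,,,,65.671,,,
189,88.147,84.203,-4.68,0,66.052,,,
190,67.586,,,,59.613,58.962,-1.10,0
191,75.088,77.172,2.70,0,50.567,51.685,2.16,0
192,67.662,,,,58.945,,,
193,69.188,69.360,0.25,0,58.711,,,
194,73.294,76.926,4.72,1,57.909,,,
195,69.996,71.502,2.11,0,50.303,,,
196,73.869,,,,51.909,,,
197,76.361,74.519,-2.47,0,61.428,,,
198,74.917,,,,54.322,,,
199,73.260,72.533,-1.00,0,53.729,,,
200,73.676,76.580,3.79,0,62.805,61.690,-1.81,0
201,68.497,70.293,2.56,0,58.049,,,
202,68.262,65.828,-3.70,0,49.883,,,
203,78.701,78.053,-0.83,0,49.585,,,
204,72.909,71.865,-1.45,1,60.753,,,
205,70.706,73.702,4.07,0,53.985,,,
206,76.912,,,,55.815,59.438,6.10,1
207,79.669,76.815,-3.72,1,60.496,,,
208,74.789,75.332,0.72,0,55.552,55.405,-0.27,0
209,79.286,79.575,0.36,0,59.179,59.612,0.73,0
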