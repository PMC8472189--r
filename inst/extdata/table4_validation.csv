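row,molecule,phyto_total,phyto_est,phyto_rel_err,estro_total,estro_est,estro_rel_err
1,4'-OH-CB97,75.468,71.34,-5.47,66.793,55.05,-17.58
2,4'-OH-CB101,74.627,62.36,-16.44,65.252,59.60,-8.66
3,4-OH-CB107,78.598,84.60,7.64,67.165,67.39,0.34
4,4-OH-CB109,75.046,67.77,-9.70,65.372,59.92,-8.34
5,3-OH-CB118,86.550,83.53,-3.49,62.666,63.70,1.65
6,4-OH-CB148,68.485,66.70,-2.61,71.272,55.92,-21.54
7,3-OH-CB153,72.700,78.53,8.02,66.310,59.69,-9.98
8,4-OH-CB162,97.896,85.20,-12.97,61.408,64.24,4.61
9,4'-OH-CB172,80.308,66.42,-17.29,65.140,55.88,-14.22
10,4-OH-CB187,75.115,72.69,-3.23,63.185,52.85,-16.36
11,4'-OH-CB199,79.422,85.35,7.46,60.988,62.00,1.66
12,4-OH-CB202,77.024,69.99,-9.13,55.911,56.65,1.32
13,3'-MeSO2-CB49,72.948,67.66,-7.25,67.760,56.88,-16.06
14,4-MeSO2-CB64,71.831,62.72,-12.68,61.242,52.25,-14.68
15,3-MeSO2-CB70,86.872,78.98,-9.08,72.756,66.08,-9.18
16,3-MeSO2-CB110,80.192,67.57,-15.74,78.504,62.03,-20.98
17,4-MeSO2-CB149,83.809,81.80,-2.40,58.452,54.16,-7.34
18,4-MeSO2-CB174,80.324,72.89,-9.26,54.488,55.18,1.27
19,P1,66.228,65.26,-1.46,70.507,69.30,-1.72
20,P1-1,104.434,65.13,-37.63,58.480,54.33,-7.10
21,P1-2,78.201,70.87,-9.38,73.265,73.99,0.99
22,P1-3,85.788,79.05,-7.85,67.833,68.90,1.57
23,P1-4,78.552,76.85,-2.17,52.126,56.28,7.97
24,P2,77.873,71.37,-8.35,60.337,49.40,-18.13
25,P2-1,83.167,75.60,-9.10,77.099,69.56,-9.78
26,P2-2,73.239,67.16,-8.30,72.490,52.34,-27.79
27,P2-3,88.294,80.53,-8.80,65.488,50.00,-23.65
28,P2-4,80.868,86.94,7.50,64.082,58.51,-8.69
29,P3,77.512,75.06,-3.17,63.670,57.49,-9.71
30,P3-1,78.478,63.60,-18.96,53.482,48.79,-8.78
31,P3-2,76.342,79.84,4.58,63.270,58.63,-7.33
32,P3-3,76.683,61.30,-20.06,72.835,58.63,-19.50
33,P3-4,77.896,79.56,2.13,55.943,52.53,-6.10
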