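row,pathway,parent,products
1,plant,PCB-3,4-CBA
2,plant,PCB-4,2-CBA
3,plant,PCB-5,"2,3-CBA"
4,plant,PCB-11,3-CBA
5,plant,PCB-31,"2,5-CBA"
6,microbial_aerobic,PCB-97,4'-OH-CB97
7,microbial_aerobic,PCB-101,4'-OH-CB101
8,microbial_aerobic,PCB-107,4-OH-CB107
9,microbial_aerobic,PCB-109,4-OH-CB109
10,microbial_aerobic,PCB-118,3-OH-CB118
11,microbial_aerobic,PCB-148,4-OH-CB148
12,microbial_aerobic,PCB-153,3-OH-CB153
13,microbial_aerobic,PCB-162,4-OH-CB162
14,microbial_aerobic,PCB-172,4'-OH-CB172
15,microbial_aerobic,PCB-187,4-OH-CB187
16,microbial_aerobic,PCB-199,4'-OH-CB199
17,microbial_aerobic,PCB-202,4-OH-CB202
18,microbial_anaerobic,PCB-90,PCB-49;PCB-68
19,microbial_anaerobic,PCB-91,PCB-51
20,microbial_anaerobic,PCB-92,PCB-52;PCB-72
21,microbial_anaerobic,PCB-95,PCB-53
22,microbial_anaerobic,PCB-99,PCB-47
23,microbial_anaerobic,PCB-101,PCB-49
24,microbial_anaerobic,PCB-102,PCB-51
25,microbial_anaerobic,PCB-130,PCB-90
26,microbial_anaerobic,PCB-132,PCB-91
27,microbial_anaerobic,PCB-135,PCB-94
28,microbial_anaerobic,PCB-137,PCB-90;PCB-99
29,microbial_anaerobic,PCB-138,PCB-99
30,microbial_anaerobic,PCB-146,PCB-90
31,microbial_anaerobic,PCB-147,PCB-91
32,microbial_anaerobic,PCB-149,PCB-102
33,microbial_anaerobic,PCB-151,PCB-95
34,microbial_anaerobic,PCB-153,PCB-99
35,microbial_anaerobic,PCB-154,PCB-100
36,microbial_anaerobic,PCB-170,PCB-130;PCB-137;PCB-138
37,microbial_anaerobic,PCB-174,PCB-149
38,microbial_anaerobic,PCB-180,PCB-153;PCB-146
39,microbial_anaerobic,PCB-183,PCB-154
40,microbial_anaerobic,PCB-187,PCB-149
41,biometabolism,PCB-49,3'-MeSO2-CB49
42,biometabolism,PCB-64,4-MeSO2-CB64
43,biometabolism,PCB-70,3-MeSO2-CB70
44,biometabolism,PCB-110,3-MeSO2-CB110
45,biometabolism,PCB-149,4-MeSO2-CB149
46,biometabolism,PCB-174,4-MeSO2-CB174
47,photodegradation,PCB-47,PCB-15
48,photodegradation,PCB-40,PCB-11
49,photodegradation,PCB-101,PCB-70
50,photodegradation,PCB-171,PCB-35
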