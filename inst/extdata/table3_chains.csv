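molecule,phytotoxicity,phytotoxicity_change,estrogen_toxicity,estrogen_toxicity_change,bioconcentration,bioconcentration_change,persistence,persistence_change,migration,migration_change
PCB-52,67.203,,64.519,,4.63,,0.989,,8.538,
52-1,90.708,34.98,65.576,1.64,3.879,-16.22,1.011,2.22,9.061,6.13
52-2,75.438,12.25,64.884,0.57,5.034,8.73,1.095,10.72,10.111,18.42
52-3,58.492,-12.96,55.954,-13.28,5.372,16.03,1.102,11.43,9.431,10.46
52-4,39.965,-40.53,69.928,8.38,1.159,-74.97,-0.831,-184.02,3.449,-59.60
P1,65.259,,69.296,,5.477,,0.811,,9.686,
P1-1,65.134,-0.19,54.331,-21.60,5.258,-4.00,0.665,-18.00,8.575,-11.47
P1-2,70.868,8.59,73.992,6.78,4.416,-19.37,0.881,8.63,8.494,-12.31
P1-3,79.052,21.14,68.901,-0.57,4.214,-23.06,0.78,-3.82,8.634,-10.86
P1-4,76.850,17.76,56.281,-18.78,4.596,-16.09,0.893,10.11,8.852,-8.61
PCB-189,88.147,,66.052,,5.440,,1.567,,11.517,
189-1,84.575,-4.05,62.105,-5.98,5.446,0.11,1.274,-18.70,10.565,-8.27
189-2,79.545,-9.76,58.150,-11.96,5.649,3.84,1.599,2.04,10.912,-5.25
189-3,84.176,-4.50,68.607,3.87,5.939,9.17,1.299,-17.10,10.702,-7.08
189-4,31.989,-63.71,59.291,-10.24,2.873,-47.19,-0.558,-135.61,4.428,-61.55
P2,71.373,,49.398,,3.446,,1.311,,4.642,
P2-1,75.601,5.92,69.555,40.81,4.439,28.82,0.694,-47.06,7.406,59.54
P2-2,67.157,-5.91,52.344,5.96,5.459,58.42,1.038,-20.82,9.928,113.87
P2-3,80.525,12.82,50.002,1.22,4.725,37.12,1.49,13.65,9.046,94.87
P2-4,86.936,21.81,58.514,18.45,5.536,60.65,1.212,-7.55,10.088,117.32
PCB-209,79.408,,54.982,,6.136,,2.191,,11.805,
209-1,85.844,8.10,50.643,-7.89,4.726,-22.98,1.85,-15.56,10.003,-15.26
209-2,77.534,-2.36,51.355,-6.60,6.204,1.11,2.079,-5.11,9.816,-16.85
209-3,61.850,-22.11,47.372,-13.84,6.079,-0.93,1.606,-26.70,10.169,-13.86
209-4,50.929,-35.86,71.124,29.36,3.190,-48.01,-0.487,-122.23,7.964,-32.54
P3,75.056,,57.487,,5.500,,1.863,,11.102,
P3-1,63.598,-15.27,48.786,-15.14,5.815,5.73,1.700,-8.75,9.383,-15.48
P3-2,79.836,6.37,58.633,1.99,5.703,3.69,1.478,-20.67,9.948,-10.39
P3-3,61.300,-18.33,58.633,1.99,5.367,-2.42,1.402,-24.75,8.608,-22.46
P3-4,79.556,6.00,52.530,-8.62,5.065,-7.91,0.949,-49.06,10.965,-1.23
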