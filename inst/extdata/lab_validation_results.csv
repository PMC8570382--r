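participant,accuracy_individual,kappa_individual,accuracy_group,kappa_group
1,0.92,0.91,0.95,0.94
2,0.94,0.90,0.95,0.91
3,0.96,0.94,0.84,0.56
4,0.96,0.96,0.82,0.82
5,0.97,0.70,0.94,0.81
6,0.97,0.94,0.99,0.79
7,0.98,0.94,0.90,0.60
8,0.99,0.97,1.00,1.00
9,0.99,0.98,0.98,0.95
10,0.99,0.99,0.99,0.98
11,1.00,1.00,0.89,0.84
12,1.00,1.00,0.91,0.75
13,1.00,1.00,0.95,0.73
14,1.00,1.00,0.92,0.88
15,1.00,1.00,0.94,0.78
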