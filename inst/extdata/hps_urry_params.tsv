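residue	lambda	sigma	charge	mass
A	0.602942	5.04	0	71.08
R	0.558824	6.56	1	156.19
N	0.588236	5.68	0	114.10
D	0.294119	5.58	-1	115.09
C	0.647060	5.48	0	103.14
Q	0.558824	6.02	0	128.13
E	0.000000	5.92	-1	129.12
G	0.573530	4.50	0	57.05
H	0.764707	6.08	0	137.14
I	0.705883	6.18	0	113.16
L	0.720589	6.18	0	113.16
K	0.382354	6.36	1	128.17
M	0.676471	6.18	0	131.19
F	0.823530	6.36	0	147.18
P	0.758824	5.56	0	97.12
S	0.588236	5.18	0	87.08
T	0.588236	5.62	0	101.10
W	1.000000	6.78	0	186.21
Y	0.897059	6.46	0	163.18
V	0.664707	5.86	0	99.07
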