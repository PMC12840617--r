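residue,hydrophobicity,hydrophilicity,mass,pk1,pk2,pi
A,1.8,-0.5,89.09,2.34,9.69,6
C,2.5,-1,121.16,1.96,10.28,5.07
D,-3.5,3,133.1,1.88,9.6,2.77
E,-3.5,3,147.13,2.19,9.67,3.22
F,2.8,-2.5,165.19,1.83,9.13,5.48
G,-0.4,0,75.07,2.34,9.6,5.97
H,-3.2,-0.5,155.16,1.82,9.17,7.59
I,4.5,-1.8,131.17,2.36,9.6,6.02
K,-3.9,3,146.19,2.18,8.95,9.74
L,3.8,-1.8,131.17,2.36,9.6,5.98
M,1.9,-1.3,149.21,2.28,9.21,5.74
N,-3.5,0.2,132.12,2.02,8.8,5.41
P,-1.6,0,115.13,1.99,10.6,6.3
Q,-3.5,0.2,146.15,2.17,9.13,5.65
R,-4.5,3,174.2,2.17,9.04,10.76
S,-0.8,0.3,105.09,2.21,9.15,5.68
T,-0.7,-0.4,119.12,2.11,9.62,5.6
V,4.2,-1.5,117.15,2.32,9.62,5.96
W,-0.9,-3.4,204.23,2.38,9.39,5.89
Y,-1.3,-2.3,181.19,2.2,9.11,5.66
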