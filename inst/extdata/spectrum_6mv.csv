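energy_MeV,probability
0.25,0.060
0.75,0.160
1.25,0.170
1.75,0.150
2.25,0.120
2.75,0.100
3.25,0.080
4.00,0.080
5.00,0.050
6.00,0.030
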