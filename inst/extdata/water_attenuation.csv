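energy_MeV,mu_over_rho,mu_en_over_rho
0.01,5.329,4.944
0.05,0.2269,0.04188
0.1,0.1707,0.02546
0.2,0.1370,0.02967
0.5,0.09687,0.03299
1.0,0.07072,0.03103
1.5,0.05754,0.02833
2.0,0.04942,0.02608
3.0,0.03969,0.02281
4.0,0.03403,0.02066
5.0,0.03031,0.01915
6.0,0.02770,0.01806
8.0,0.02429,0.01658
10.0,0.02219,0.01566
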