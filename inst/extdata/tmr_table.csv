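depth_cm,S4,S6,S8,S10,S15,S20,S30
1.5,1.000,1.000,1.000,1.000,1.000,1.000,1.000
5,0.873,0.881,0.887,0.893,0.903,0.910,0.918
10,0.706,0.719,0.730,0.739,0.757,0.770,0.786
15,0.563,0.578,0.592,0.604,0.628,0.645,0.667
20,0.448,0.464,0.478,0.491,0.517,0.536,0.560
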