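X,Y2,Y4,Y6,Y8,Y10,Y15,Y20,Y30,Y40
2,1.002848,1.002476,1.002104,1.001732,1.00136,1.00043,0.9995,0.99764,0.99578
4,1.002476,1.002112,1.001748,1.001384,1.00102,1.00011,0.9992,0.99738,0.99556
6,1.002104,1.001748,1.001392,1.001036,1.00068,0.99979,0.9989,0.99712,0.99534
8,1.001732,1.001384,1.001036,1.000688,1.00034,0.99947,0.9986,0.99686,0.99512
10,1.00136,1.00102,1.00068,1.00034,1,0.99915,0.9983,0.9966,0.9949
15,1.00043,1.00011,0.99979,0.99947,0.99915,0.99835,0.99755,0.99595,0.99435
20,0.9995,0.9992,0.9989,0.9986,0.9983,0.99755,0.9968,0.9953,0.9938
30,0.99764,0.99738,0.99712,0.99686,0.9966,0.99595,0.9953,0.994,0.9927
40,0.99578,0.99556,0.99534,0.99512,0.9949,0.99435,0.9938,0.9927,0.9916
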