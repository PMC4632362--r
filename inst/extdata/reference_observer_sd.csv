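patient,CT,CTMR,MR
1,3.59,4.17,3.33
2,3.95,5.19,3.32
3,4.61,3.75,1.36
4,4.36,4.82,1.15
5,4.29,3.16,3.37
6,2.01,2.81,0.48
7,1.84,2.84,2.15
8,8.65,4.87,2.99
9,5.63,3.91,2.40
10,1.62,0.83,0.93
11,8.59,4.42,5.93
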