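bin,bin_lo,bin_hi,n_dementia,n_unclear,n_non
1,0.0,0.1,3,1,26
2,0.1,0.2,2,1,7
3,0.2,0.3,2,0,8
4,0.3,0.4,6,1,3
5,0.4,0.5,3,2,5
6,0.5,0.6,5,0,5
7,0.6,0.7,5,1,4
8,0.7,0.8,6,0,4
9,0.8,0.9,8,0,2
10,0.9,1.0,7,2,1
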