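subject,accuracy,recall,far
1,73.42,70.33,23.50
2,72.05,69.75,25.65
3,60.84,60.22,38.52
4,75.11,76.00,25.77
5,80.74,82.11,20.63
6,78.35,75.21,18.51
7,73.12,74.84,28.60
8,80.67,78.28,16.93
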