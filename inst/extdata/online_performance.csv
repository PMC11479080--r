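subject,accuracy,recall,far,response_time_ms
1,79.38,82.50,23.73,674.75
2,91.41,91.67,8.85,452.73
3,90.08,94.58,14.43,363.88
4,90.29,95.42,14.84,392.14
5,89.17,87.50,9.17,368.57
6,89.89,90.42,10.65,398.16
7,90.06,88.75,8.63,425.35
8,90.20,91.67,11.27,380.00
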