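subject,movement,imagery
S1,86.90,81.79
S2,82.32,79.23
S3,81.47,70.94
S4,85.79,79.29
S5,76.23,73.97
S6,89.21,82.93
S7,84.79,78.56
S8,82.29,81.47
S9,78.04,73.96
S10,86.45,79.79
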