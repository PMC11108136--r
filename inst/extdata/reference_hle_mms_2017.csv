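age,sex,hle_mms,le_mms
0,female,39.94,85.82
0,male,42.87,80.58
65,female,2.43,22.31
65,male,2.17,18.86
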