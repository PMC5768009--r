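"hu","wer"
-1000,0.001
-200,0.82
0,1
200,1.12
1000,1.66
3000,2.6
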