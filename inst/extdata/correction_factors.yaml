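anchors:
- 10.0
- 100.0
- 250.0
F_pH:
- 3.0
- 8.0
- 17.0
F_pO:
- 1.0
- 1.0
- 1.0
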