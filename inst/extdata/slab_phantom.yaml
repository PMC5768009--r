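kind: slab_hetero
extents:
- 200.0
- 200.0
- 350.0
inserts:
- lo:
  - -100.0
  - -100.0
  - 20.0
  hi:
  - 0.0
  - 100.0
  - 50.0
  wer: 2.0
- lo:
  - 0.0
  - -100.0
  - 60.0
  hi:
  - 100.0
  - 100.0
  - 90.0
  wer: 0.001
- lo:
  - -100.0
  - -100.0
  - 100.0
  hi:
  - 100.0
  - 100.0
  - 120.0
  wer: 2.0
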