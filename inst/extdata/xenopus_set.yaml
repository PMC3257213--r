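E:
- 0.1
- 0.0025
- 0.0025
Ep:
- 0.1
- 0.00025
- 0.1
K:
- 100.0
- 0.25
- 0.25
Kp:
- 100.0
- 0.25
- 0.25
P:
- 1.0
- 10.0
- 0.025
KB: 0.0833
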