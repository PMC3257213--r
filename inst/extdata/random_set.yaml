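E:
- 4.87
- 32.560000000000002
- 0.28
Ep:
- 0.05
- 1.26
- 0.29
K:
- 5.07
- 28.18
- 0.04
Kp:
- 66.340000000000003
- 9.33
- 0.59
P:
- 0.21
- 3.43
- 0.42
KB: 0.05
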