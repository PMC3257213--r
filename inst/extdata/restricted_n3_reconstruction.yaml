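motif: vertical
'n': 3
tie_cycles_to_3: no
ranges:
  E1:
    min: 0.01
    max: 100.0
    scale: log
  E2:
    min: 0.01
    max: 100.0
    scale: log
  E3:
    min: 0.01
    max: 1.0
    scale: log
  Ep1:
    min: 0.01
    max: 100.0
    scale: log
  Ep2:
    min: 0.01
    max: 100.0
    scale: log
  Ep3:
    min: 0.01
    max: 1.0
    scale: log
  K1:
    min: 0.01
    max: 0.1
    scale: log
  K2:
    min: 1.0
    max: 10.0
    scale: log
  K3:
    min: 0.01
    max: 0.1
    scale: log
  Kp1:
    min: 10.0
    max: 100.0
    scale: log
  Kp2:
    min: 0.01
    max: 100.0
    scale: log
  Kp3:
    min: 0.01
    max: 0.1
    scale: log
  P1:
    min: 1.0
    max: 10.0
    scale: log
  P2:
    min: 0.1
    max: 10.0
    scale: log
  P3:
    min: 0.1
    max: 1.0
    scale: log
  KB:
    min: 0.01
    max: 100.0
    scale: log
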