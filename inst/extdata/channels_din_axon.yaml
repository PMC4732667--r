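leak:
  kind: ohmic
  density: 0.01
  reversal: -57.0
  gates: []
na:
  kind: ohmic
  density: 150.0
  reversal: 50.0
  gates:
  - name: m
    exponent: 3
    alpha:
    - 2.0
    - 0.0
    - 1.0
    - 33.0
    - -5.0
    beta:
    - 2.0
    - 0.0
    - 1.0
    - 33.0
    - 5.0
  - name: h
    exponent: 1
    alpha:
    - 0.25
    - 0.0
    - 1.0
    - 52.0
    - 7.0
    beta:
    - 0.25
    - 0.0
    - 1.0
    - 52.0
    - -7.0
kf:
  kind: ohmic
  density: 40.0
  reversal: -80.0
  gates:
  - name: 'n'
    exponent: 2
    alpha:
    - 0.4
    - 0.0
    - 1.0
    - 20.0
    - -6.0
    beta:
    - 0.4
    - 0.0
    - 1.0
    - 20.0
    - 6.0
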