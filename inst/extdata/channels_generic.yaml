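leak:
  kind: ohmic
  density: 0.3
  reversal: -54.387
  gates: []
na:
  kind: ohmic
  density: 120.0
  reversal: 50.0
  gates:
  - name: m
    exponent: 3
    alpha:
    - -4.0
    - -0.1
    - -1.0
    - 40.0
    - -10.0
    beta:
    - 4.0
    - 0.0
    - 0.0
    - 65.0
    - 18.0
  - name: h
    exponent: 1
    alpha:
    - 0.07
    - 0.0
    - 0.0
    - 65.0
    - 20.0
    beta:
    - 1.0
    - 0.0
    - 1.0
    - 35.0
    - -10.0
k:
  kind: ohmic
  density: 36.0
  reversal: -77.0
  gates:
  - name: 'n'
    exponent: 4
    alpha:
    - -0.55
    - -0.01
    - -1.0
    - 55.0
    - -10.0
    beta:
    - 0.125
    - 0.0
    - 0.0
    - 65.0
    - 80.0
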