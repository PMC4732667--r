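leak:
  kind: ohmic
  density: 0.01
  reversal: -57.0
  gates: []
na:
  kind: ohmic
  density: 40.0
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
  density: 12.0
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
ks:
  kind: ohmic
  density: 3.0
  reversal: -80.0
  gates:
  - name: ks
    exponent: 2
    alpha:
    - 0.0333333
    - 0.0
    - 1.0
    - 35.0
    - -6.0
    beta:
    - 0.0333333
    - 0.0
    - 1.0
    - 35.0
    - 6.0
ca:
  kind: ghk
  permeability: 1.5e-06
  ca_in: 0.0001
  ca_out: 10.0
  temperature: 293.15
  gates:
  - name: mca
    exponent: 2
    alpha:
    - 0.25
    - 0.0
    - 1.0
    - 25.0
    - -7.0
    beta:
    - 0.25
    - 0.0
    - 1.0
    - 25.0
    - 7.0
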