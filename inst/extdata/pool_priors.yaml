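water:
  amplitude:
  - 0.8
  - 0.02
  - 1.0
  center:
  - 0.0
  - -0.01
  - 0.01
  width:
  - 2.8
  - 1.5
  - 5.0
hydroxyl:
  amplitude:
  - 0.05
  - 0.0
  - 0.3
  center:
  - 1.0
  - 0.99
  - 1.01
  width:
  - 1.2
  - 0.6
  - 2.5
amine:
  amplitude:
  - 0.05
  - 0.0
  - 0.3
  center:
  - 2.0
  - 1.99
  - 2.01
  width:
  - 1.8
  - 1.0
  - 3.5
amide:
  amplitude:
  - 0.05
  - 0.0
  - 0.3
  center:
  - 3.5
  - 3.49
  - 3.51
  width:
  - 2.0
  - 1.0
  - 3.5
rNOE:
  amplitude:
  - 0.05
  - 0.0
  - 0.4
  center:
  - -3.5
  - -3.51
  - -3.49
  width:
  - 3.5
  - 2.0
  - 5.5
MT:
  amplitude:
  - 0.1
  - 0.0
  - 0.5
  center:
  - -2.4
  - -2.41
  - -2.39
  width:
  - 25.0
  - 15.0
  - 60.0
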