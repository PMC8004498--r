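'n': 4
alphabets:
- - '0'
  - '1'
- - '0'
  - '1'
- - '0'
  - '1'
- - '0'
  - '1'
demes:
- a
- b
migration:
  backward:
    a:
      a: 0.5
      b: 0.5
    b:
      a: 0.5
      b: 0.5
recombination:
- partition:
  - 1
  - 2
  - 3
  - 4
  prob: 1/2
- partition:
  - - 1
    - 2
  - - 3
    - 4
  prob: 1/10
- partition:
  - - 1
    - 2
    - 3
    - 4
  prob: 2/5
initial:
  a:
  - 0.0625
  - 0.0625
  - 0.0625
  - 0.0625
  - 0.0625
  - 0.0625
  - 0.0625
  - 0.0625
  - 0.0625
  - 0.0625
  - 0.0625
  - 0.0625
  - 0.0625
  - 0.0625
  - 0.0625
  - 0.0625
  b:
  - 0.0625
  - 0.0625
  - 0.0625
  - 0.0625
  - 0.0625
  - 0.0625
  - 0.0625
  - 0.0625
  - 0.0625
  - 0.0625
  - 0.0625
  - 0.0625
  - 0.0625
  - 0.0625
  - 0.0625
  - 0.0625
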