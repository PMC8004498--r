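'n': 2
alphabets:
- - A
  - B
- - A
  - B
demes:
- deme1
- deme2
migration:
  backward:
    deme1:
      deme1: 0.898636390319202
      deme2: 0.101363609680798
    deme2:
      deme1: 0.643427091856293
      deme2: 0.356572908143707
recombination:
- partition:
  - 1
  - 2
  prob: 0.921243328897672
- partition:
  - - 1
    - 2
  prob: 0.078756671102328
generator:
  deme1:
    deme1: -1.399237499337942
    deme2: 1.399237499337942
  deme2:
    deme1: 2.092992029727136
    deme2: -2.092992029727136
rates:
- partition:
  - 1
  - 2
  rate: 0.056345866172557
initial:
  deme1:
  - 0.237797969156227
  - 0.355850696355771
  - 0.192707200580926
  - 0.213644133907077
  deme2:
  - 0.087862821299203
  - 0.803623297167599
  - 0.086465603524422
  - 0.022048278008777
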