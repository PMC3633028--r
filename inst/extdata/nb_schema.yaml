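outcome: Outcome
attributes:
  Age:
    kind: nominal
    values: ["<1", ">=1"]
  INSS:
    kind: nominal
    values: ["1", "2", "3", "4", "4s"]
  MYCN:
    kind: nominal
    values: [normal, amplified]
  NBhypo:
    kind: nominal
    values: [Low, High]
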