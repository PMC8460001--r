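ESR1:
  ru:
    breaks:
    - 0.0
    - 1.1
    labels:
    - Negative
    - Low Positive
    - High Positive
  ihc:
    breaks:
    - 1.0
    - 50.0
    labels:
    - Negative
    - Low Positive
    - High Positive
PGR:
  ru:
    breaks:
    - 0.0
    - 0.5
    labels:
    - Negative
    - Low Positive
    - High Positive
  ihc:
    breaks:
    - 1.0
    - 20.0
    labels:
    - Negative
    - Low Positive
    - High Positive
ERBB2:
  ru:
    breaks:
    - -0.7
    - 0.0
    labels:
    - Negative
    - Equivocal
    - Positive
  ihc:
    ordinal:
      '0': Negative
      1+: Negative
      2+: Equivocal
      3+: Positive
MKI67:
  ru:
    breaks: 0.0
    labels:
    - Low
    - High
  ihc:
    breaks: 20.0
    labels:
    - Low
    - High
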