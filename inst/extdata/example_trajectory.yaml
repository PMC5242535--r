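# Example trajectory overrides: a milder disease model with more missing
# behavioural data. Any field omitted here keeps its package default.
missingness: 0.08
outlier_rate: 0.02
regions:
  striatum:
    HD:
      decline: 0.15
  cortex:
    HD:
      decline: 0.08
behaviour:
  locomotor_activity:
    deficit:
      male: 0.20
      female: 0.25
noise:
  residual_cv: 0.06
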