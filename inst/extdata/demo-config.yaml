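# Demonstration run: small simulated cohort, a reduced variant series and a
# four-region thickness sweep.
seed: 20
generator:
  n_participants: 300
  factor_scheme: one_factor
preprocess:
  winsorize_sd: 3
  winsorize_increment: 0.01
variants:
  - one_factor:hormones_saliva_only
  - one_factor:full_multimethod
brain:
  variants:
    - one_factor:full_multimethod
  age: [none]
  regions: [lh_cuneus, rh_cuneus, lh_lateraloccipital, lh_insula]
  estimator: ml
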