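# Bundled demonstration configuration: a small synthetic cohort with one
# planted drug-sensitive gene (G0001, carried by S01 and S02) and one
# planted altered driver gene (G0050) adjacent to it in the interaction
# network. `out_dir` is supplied at run time.
seed: 42
cohort:
  n_samples: 12
  n_drugs: 40
  n_genes: 120
  n_expression_genes: 200
  n_rppa: 50
plates:
  n_doses: 7
  dilution_factor: 3
  top_conc: 10
  noise_sd: 0.05
  effect: 0.6
planted:
  sensitive_gene: G0001
  carrier_samples: [S01, S02]
  driver_gene: G0050
  drugs_per_planted_gene: 8
scoring:
  n_perm: 1000
  fit_kind: ols
propagation:
  c: 0.7
  n_rewired: 1000
  alpha: 0.05
expression:
  within_sd: 0.3
combinations:
  n_combos: 10
  potency_ratio: 0.7
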