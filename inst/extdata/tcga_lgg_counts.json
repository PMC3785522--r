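{
  "description": "Static counts from a public low-grade-glioma cohort query (no live API access)",
  "n_lgg_complete": 213,
  "n_codeleted": 64,
  "n_codeleted_cic_mutant": 33,
  "n_codeleted_fubp1_mutant": 20,
  "n_codeleted_fubp1_and_cic": 14,
  "reported_fubp1_cic_odds_ratio": 3.79,
  "reported_fubp1_cic_p": 6e-04,
  "expression_outlier_threshold_fold": 2.5,
  "note": "The 2x2 table behind the reported odds ratio is not reconstructible from these margins; the value is recorded for reference, not used as a golden test."
}
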