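# extdata

- `synthetic_indicator_covariance.tsv` — **synthetic** 6x6 covariance
  matrix of the adjusted indicator traits (QG, FOR, MARB, JC, TD, CT),
  a stand-in for the study covariance matrix that is not distributable
  with the package sources.  Generated from the final two-latent model
  at structural coefficient 0.28 (indicator scales proportional to the
  published trait SDs, strongest loadings on MARB and TD) plus Wishart
  sampling noise (df 50,000, seed 20180532).  Nominal sample size
  n = 726.  Used by the acceptance test of the SEM refit path.
- `example_config.json` — ready-to-run pipeline configuration for the
  CLI (`Rscript inst/cli/semscan.R all --config ... --out ...`).
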