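{
  "simulation": {
    "n_founders": 150,
    "n_generations": 4,
    "n_sires": 40,
    "n_animals_target": 700,
    "n_snps": 600,
    "n_chromosomes": 6,
    "seed": 11
  },
  "classifier": { "assoc_threshold": 2, "strong_threshold": 5 },
  "qc": { "maf_min": 0.05, "callrate_min": 0.9 },
  "blend_alpha": 0.95,
  "window_size": 20,
  "seed": 11
}
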