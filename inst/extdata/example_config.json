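{
  "seed": 7,
  "simulate": {
    "n_birds": 1500,
    "n_background_snps": 1000,
    "block_marker_count": 60
  },
  "scan": {
    "strata": ["male", "female"],
    "min_depth": 9,
    "c_low": 0.20,
    "c_high": 0.40,
    "max_gap_bp": 50000,
    "min_snps_low": 20
  },
  "assoc": {
    "loci": ["intron6", "exon8", "combined"],
    "n_tests": 3
  },
  "expr": {
    "reference_group": "G1",
    "reference_gene": "TBP"
  }
}
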