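{
  "seed": 1,
  "sim": {
    "n_taxon_groups": 4,
    "orfs_per_group": 500,
    "orf_length": 300,
    "library_size": 25000,
    "dispersion": 0.1,
    "de_fraction": 0.1,
    "de_log2fc": 3,
    "subpop_divergence": 0.05,
    "subpop_mix": [0.8, 0.2],
    "error_rate": 0.001,
    "read_length": 100,
    "n_planted_snvs": 10
  },
  "de": {
    "min_total": 5,
    "alpha": 0.05
  },
  "pidshift": {
    "min_identity": 60,
    "alpha": 0.05,
    "min_reads": 10
  },
  "snv": {
    "min_depth": 4,
    "min_alt": 2,
    "min_af": 0.05,
    "sweep_hi": 0.9,
    "sweep_lo": 0.5
  },
  "cluster": {
    "k": 4,
    "min_shared": 3,
    "inflation": 1.5,
    "min_members": 10,
    "min_abs_lfc": 2.5
  },
  "biomarker": {
    "pseudocount": 1,
    "delta": 0.5
  }
}
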