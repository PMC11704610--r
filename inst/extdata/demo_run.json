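{
  "seed": 2024,
  "sim": {
    "n_genes": 3,
    "n_cells": 80,
    "n_replicates": 2,
    "extrinsic_coupling": 1,
    "capture_mean": 0.1,
    "amplification": 2
  },
  "qc": {
    "min_genes": 1,
    "min_umi": 1
  },
  "filter": {
    "n_perm": 500,
    "min_cells": 20
  }
}
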