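{
  "guides": [
    {"spacer_id": "G20", "complementarity_bp": 20, "r": 0.026, "r_sd": 0.003},
    {"spacer_id": "G14", "complementarity_bp": 14, "r": 0.056, "r_sd": 0.001}
  ],
  "promoters": {
    "ref_name": "P127", "target_name": "PPhlF",
    "strength_fold": 2.6, "strength_fold_sd": 0.2,
    "gamma_star_ref": 0.32, "gamma_star_ref_sd": 0.04
  },
  "kinetics": {"gamma0": 20, "rebinding_rate": 2000, "koff": 0, "delta": 1},
  "copy_number": {"tC": 60, "tD": 20, "td": 30, "phi": 0.66},
  "mc": {"n_draws": 100000, "seed": 1},
  "simulation": {"n_cells": 1000, "t_end": 120, "burn_in": 60, "seed": 1},
  "alpha": 0
}
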