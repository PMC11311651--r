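{
  "seed": 1,
  "geometry": {
    "n_posts": 16,
    "post_diameter_um": 150,
    "post_gap_um": 200,
    "channel_width_um": 1000,
    "channel_length_um": 30000
  },
  "calibration": {
    "um_per_px": 1
  },
  "segmentation": {
    "min_area_um2": 50,
    "threshold_method": "otsu"
  },
  "simulation": {
    "seed": 1,
    "geometry": [],
    "um_per_px": 1,
    "n_cells": 400,
    "steps_per_day": 24,
    "ic50_uM": 1,
    "clustering_radius_um": 150,
    "arms": [
      {
        "cell_line": "T24like",
        "phenotype": "invasive",
        "drift_um_per_step": 7,
        "diffusion_um": 6,
        "doses": 0,
        "n_chips": 3,
        "days": [1, 2]
      },
      {
        "cell_line": "J82like",
        "phenotype": "invasive",
        "drift_um_per_step": 8,
        "diffusion_um": 6,
        "doses": 0,
        "n_chips": 3,
        "days": [1, 2]
      },
      {
        "cell_line": "RT4like",
        "phenotype": "non_invasive",
        "drift_um_per_step": 0,
        "diffusion_um": 2,
        "doses": 0,
        "n_chips": 3,
        "days": [1, 2]
      }
    ],
    "render": {
      "enabled": false,
      "psf_sigma_um": 4,
      "snr": 20,
      "labeled_fraction": 1,
      "peak": 1000,
      "background": 100,
      "bits_per_sample": 16
    },
    "out_dir": {},
    "keep_states": false
  },
  "stats": {
    "alpha": 0.05
  },
  "output": {
    "dir": "bladderchip_out"
  }
}
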