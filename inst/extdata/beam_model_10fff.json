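{
  "format_version": 1,
  "energy_mode": "10FFF",
  "provenance": "Published Versa HD best-fit parameters (source, OAR, kernel, leaf end, MLC factors); geometry values are package defaults (assumptions).",
  "source": {
    "amplitudes": [0.0158, 0.0398],
    "sigma_x": [2.7368, 0.6671],
    "sigma_y": [2.524, 0.5644],
    "plane_z": 6
  },
  "oar": {
    "coeffs": [0.50882, -0.011488, -0.0030966, 0.0002812, -7.0324e-06],
    "valid_radius": 22
  },
  "kernel": {
    "amplitudes": [1.0385, 0.0298, 0.0033],
    "sigmas": [0.2421, 1.3446, 8.3493]
  },
  "leaf_end": {
    "alpha": 0.7,
    "beta": 0.24,
    "soft_range": 1
  },
  "mlc": {
    "bulk": 0.01,
    "interleaf": 0.01,
    "tongue_and_groove": 0.01,
    "tg_width_iso": 0.026,
    "interleaf_width_iso": 0.03,
    "leaf_width_iso": 0.5
  },
  "geometry": {
    "sad": 100,
    "z_mlc": 33,
    "z_jaw": 43,
    "source_plane_z_ff": 12.5,
    "source_plane_z_fff": 6
  }
}
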