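{
  "format_version": 1,
  "energy_mode": "6FFF",
  "provenance": "Published Versa HD best-fit parameters (source, OAR, kernel, leaf end, MLC factors); geometry values are package defaults (assumptions).",
  "source": {
    "amplitudes": [0.022, 0.0465],
    "sigma_x": [3.3579, 0.6471],
    "sigma_y": [3.304, 0.6049],
    "plane_z": 6
  },
  "oar": {
    "coeffs": [0.55049, -0.0021479, -0.0034245, 0.00025978, -6.0768e-06],
    "valid_radius": 22
  },
  "kernel": {
    "amplitudes": [0.8709, 0.0178, 0.0032],
    "sigmas": [0.2241, 1.4376, 8.4279]
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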