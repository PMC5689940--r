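{
  "format_version": 1,
  "energy_mode": "6FF",
  "provenance": "Published Versa HD best-fit source and MLC parameters; kernel is the same-nominal-energy FFF kernel carried as a nominal stand-in (no FF kernel was published); geometry values are package defaults (assumptions).",
  "source": {
    "amplitudes": [0.0511, 0.0537],
    "sigma_x": [4.2684, 1.0977],
    "sigma_y": [3.2619, 0.9659],
    "plane_z": 12.5
  },
  "oar": null,
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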