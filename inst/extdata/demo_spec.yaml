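# Demo synthetic specification: two Gaussian hydration sites in the first
# shell of the built-in pseudo-solute over dilute bulk, small enough to
# simulate in seconds.
sites:
  - {"x": 4.3, "y": 0.0, "z": 0.0, "occupancy": 0.95, "sigma": 0.14}
  - {"x": 0.0, "y": 4.3, "z": 0.0, "occupancy": 0.80, "sigma": 0.18}
box: [-6.0, -6.0, -6.0, 6.0, 6.0, 6.0]
bulk_density: 0.02
n_frames: 300
seed: 11
solute: true
pseudo:
  n_structures: 5
  jitter_sigma: 0.15
  detect_prob: 1.0
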