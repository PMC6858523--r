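{
  "h": {
    "8": [-32.4, -14.8],
    "1": -13.6
  },
  "K": 1.75,
  "repulsion_a": 4,
  "repulsion_d": 0.33,
  "n_valence": {
    "8": 6,
    "1": 1
  }
}
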