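{
  "h": {
    "6": [-21.4, -11.4]
  },
  "K": 1.75,
  "repulsion_a": 130,
  "repulsion_d": 0.35,
  "n_valence": {
    "6": 4
  }
}
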