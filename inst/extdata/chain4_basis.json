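{
  "name": "toy-chain4",
  "elements": {
    "6": [
      {
        "l": 0,
        "exp": [3, 0.7],
        "coef": [0.5, 0.6]
      },
      {
        "l": 1,
        "exp": [1.1, 0.3],
        "coef": [0.5, 0.6]
      }
    ]
  }
}
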