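{
  "name": "toy-h2",
  "elements": {
    "1": [
      {
        "l": 0,
        "exp": [1.3097, 0.2331],
        "coef": [0.4301, 0.6789]
      }
    ]
  }
}
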