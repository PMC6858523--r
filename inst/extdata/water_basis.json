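{
  "name": "toy-water",
  "elements": {
    "8": [
      {
        "l": 0,
        "exp": [5.03, 1.17],
        "coef": [0.45, 0.63]
      },
      {
        "l": 1,
        "exp": [1.45, 0.35],
        "coef": [0.51, 0.61]
      }
    ],
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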