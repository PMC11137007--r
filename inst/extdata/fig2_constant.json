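{
  "rates": {
    "p": {"family": "constant", "level": 1},
    "h": {"family": "constant", "level": 2},
    "b": {"family": "constant", "level": 2},
    "u": 0.0001
  },
  "season": {"T": 1, "L0": 1, "s_max": 0.132, "n_steps": 20000}
}
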