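{
  "experiment": "conflict1d",
  "seed": 1,
  "d": 1,
  "p": 0.5,
  "box_halfwidth": 10,
  "n_events": 150000
}
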