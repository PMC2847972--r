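{
  "node_ages": { "ATPt": 7.3, "ATE": 15.5, "ATP": 19.6, "ATN": 23.7 },
  "reference": "tomato",
  "chromosome_number": 12
}
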