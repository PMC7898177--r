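{
  "seed": 7,
  "design": { "n_per_cell": 10 },
  "participant": { "rep_coding": "symmetric" },
  "analysis": { "alpha": 0.05 }
}
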