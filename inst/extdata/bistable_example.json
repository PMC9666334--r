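{
  "a": 0.2,
  "variant": "standard",
  "basins": { "T_init": 80, "resolution": 101 }
}
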