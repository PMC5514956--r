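{
  "mode": "demo",
  "n_tace": 80,
  "n_combo": 40,
  "seed": 1,
  "filters": ["0", "1.0", "1.5"],
  "outdir": "texstrat_demo_out"
}
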