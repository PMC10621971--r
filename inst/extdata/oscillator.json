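{
  "builder": {
    "name": "oscillator",
    "params": { "k": 1, "r0": 1, "m": 1, "displacement": 0.4, "dt": 0.005 }
  },
  "run": { "steps": 1000, "stride": 100, "checkpoint_stride": 500,
           "out_dir": "oscillator_out" }
}
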