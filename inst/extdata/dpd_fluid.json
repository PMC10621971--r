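{
  "seed": 7,
  "universe": { "dims": [8, 8, 8], "cutoff": 1, "dt": 0.01,
                "boundary": ["periodic", "periodic", "periodic"] },
  "types": [
    { "name": "fluid", "mass": 1, "dynamics": "newtonian", "species": ["dye"] }
  ],
  "potentials": {
    "dpd_main": { "kind": "dpd",
                  "params": { "alpha": 25, "gamma": 4.5, "sigma": 3, "rc": 1 } }
  },
  "bindings": [
    { "type_a": "fluid", "type_b": "fluid", "potential": "dpd_main" }
  ],
  "particles": [
    { "type": "fluid", "positions": [
      [1.0, 1.0, 1.0], [1.8, 1.0, 1.0], [2.6, 1.0, 1.0], [3.4, 1.0, 1.0],
      [4.2, 1.0, 1.0], [1.0, 1.7, 1.4], [1.8, 1.7, 1.4], [2.6, 1.7, 1.4],
      [3.4, 1.7, 1.4], [4.2, 1.7, 1.4], [1.0, 2.4, 1.8], [1.8, 2.4, 1.8],
      [2.6, 2.4, 1.8], [3.4, 2.4, 1.8], [4.2, 2.4, 1.8]
    ],
      "species": { "dye": [1, 1, 1, 1, 1, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0] } }
  ],
  "flux_rules": [
    { "species": "dye", "type_a": "fluid", "type_b": "fluid",
      "kind": "fick", "k": 1, "r_cutoff": 1 }
  ],
  "run": { "steps": 500, "stride": 50, "out_dir": "dpd_out" }
}
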