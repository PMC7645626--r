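{
  "geometry": {"r1": 1.1e-4, "r2": 1.5e-4, "R_module": 0.0315,
               "L": 0.15, "n": 9950},
  "membrane": {"porosity": 0.40, "tortuosity": 2.2},
  "solute": "IP",
  "flows": {"Q_aq_lpm": 50, "Q_org_lpm": 50,
            "configuration": "feed_in_tube"},
  "numerics": {"nr": [48, 24, 48], "nz": 200, "grading": 1.15,
               "scheme": "upwind"}
}
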