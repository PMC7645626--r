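# Canonical single-fiber extraction case (ibuprofen into octanol).
geometry:
  r1: 1.1e-4        # fiber inner radius, m
  r2: 1.5e-4        # fiber outer radius, m
  R_module: 0.0315  # module radius, m
  L: 0.15           # fiber length, m
  n: 9950           # fibers in the module
membrane:
  porosity: 0.40
  tortuosity: 2.2
solute: IP          # or 4-IBAP, or a mapping with D_aq/D_org/m/C0
flows:
  Q_aq_lpm: 50      # module totals, L/min
  Q_org_lpm: 50
  configuration: feed_in_tube
numerics:
  nr: [48, 24, 48]
  nz: 200
  grading: 1.15
  scheme: upwind
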