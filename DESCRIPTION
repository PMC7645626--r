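Package: membrex
Title: Mechanistic Simulation of Hollow-Fiber Membrane Contactor Extraction
Version: 1.0.0
Authors@R:
    person("Membrex", "Developers", email = "membrex@example.org",
           role = c("aut", "cre"))
Description: Steady-state mechanistic simulation of non-dispersive
    liquid-liquid extraction in hollow-fiber membrane contactors, with
    built-in scenarios for removing ibuprofen and its toxic metabolite
    4-isobutylacetophenone from water into octanol.  A single fiber and its
    Happel free-surface envelope represent the bundle; the axisymmetric
    steady convection-diffusion equation is discretized by a conservative
    finite-volume scheme over the coupled tube, membrane and shell domains,
    with a partition-coefficient concentration jump at the aqueous/organic
    interface and counter-current analytic laminar velocity profiles.
    Includes mesh-independence studies, classical solver verification
    oracles (Graetz series, annular conduction), mass-balance audits,
    parameter sweeps (flow rate, porosity, fiber count, flow arrangement)
    and a command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
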