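Package: ncxdyn
Title: Dynamics of the Sodium-Calcium Exchanger in Thin Astrocyte Processes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Kinetic model of the plasma-membrane sodium-calcium exchanger
    (NCX) with allosteric regulation by cytosolic sodium and calcium, in
    Hodgkin-Huxley-style gating form. Provides the exchanger flux and its
    gating kinetics as pure functions, point and clamped-sodium cell models
    with stimulation protocols, phase-plane tools (nullclines, equilibria,
    basins of attraction, bistability maps over membrane potential and
    internal sodium), and a one-dimensional reaction-diffusion model of a
    thin astrocytic process reproducing sodium-dependent amplification and
    anisotropic spreading of calcium transients. Includes a command-line
    interface for reproducible simulation runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
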