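Package: gridlock
Title: Velocity-Coupled Grid-Cell Attractor Modules
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulator and analysis toolkit for modular continuous-attractor
    models of grid cells. Builds double-ring (1D) and four-population torus
    (2D) attractor networks with velocity integration, couples modules through
    a linear velocity readout that suppresses relative drift while leaving
    every combination of module phases a steady state, and provides the
    accompanying analysis machinery: linear response tensors and stability
    screens, phase-reduction integration, phase diffusion tensors of the
    Poisson-spiking dynamics, a maximum-likelihood spike decoder with an
    exponential temporal kernel, and synthetic foraging trajectories with
    noisy velocity drives.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
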