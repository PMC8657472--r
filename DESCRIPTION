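Package: fractalflow
Title: Fractal Ladder-Circuit Simulation of Aortic and Arteriolar Blood Flow
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates pulsatile arterial blood flow with an infinite-level
    self-similar (fractal) ladder-circuit analogue of the Windkessel model.
    The admittance of the infinite ladder is the fixed point of a quadratic
    hypercell equation; its closed-form convolution kernels (a Gaussian-type
    kernel with quadratic quotient for the aorta and an exponentially
    weighted modified-Bessel kernel for the arteriole) modulate a
    two-harmonic pulse-pressure input to produce flow responses. Includes a
    finite-ladder continued-fraction oracle, exponentially modulated
    Riemann-Liouville half-order operators, and flow analytics (reflux
    detection, pressure-flow hysteresis loops, phase lag, stable-modulation
    sweeps), with tidy tabular outputs and ggplot2 visualisations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
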