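Package: polarflow
Title: Cytosolic Flow and Pattern Formation in Mass-Conserving Reaction-Diffusion Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulator and analysis toolkit for a one-dimensional two-component
    mass-conserving reaction-diffusion system with cytosolic advection, a
    conceptual model of cell polarity. Provides the reaction kinetics and
    phase-plane geometry (nullclines, local equilibria), linear stability
    analysis of homogeneous states under uniform flow (dispersion relations,
    unstable bands, the flow-modified mass-redistribution instability
    criterion, slow- and fast-flow limits), a conservative finite-volume
    method-of-lines integrator with uniform or parabolic switchable flow, and
    pattern post-processing: peak tracking and propagation speed, phase-plane
    loop diagnostics, mesa/peak classification, and regional lateral
    instability detection. Results are returned as tibbles with broom-style
    tidy()/glance() methods and ggplot2 autoplot() methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    yaml,
    readr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
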