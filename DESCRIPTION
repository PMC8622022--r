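Package: selkovsync
Title: Drive-Response Synchronization of the Selkov Glycolysis
    Reaction-Diffusion Model
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Simulates the two-species Selkov model of glycolytic
    oscillations with diffusion on one- and two-dimensional domains with
    zero-flux (Neumann) boundaries, and synchronizes a controlled
    response copy to an autonomous drive system through a linear
    full-state feedback law whose gain is constructed from a Lyapunov
    stability argument.  Provides linear (Turing) stability analysis of
    the homogeneous steady state, explicit finite-difference time
    integration with CFL control, synchronization-error diagnostics
    (L2 norm, Lyapunov functional, sup-norm boundedness and positivity
    monitors), reproducible initial-condition fixtures, YAML run
    configurations, and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
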