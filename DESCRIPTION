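Package: chiptwin
Title: Digital Twins of Liver-on-Chip Drug Depletion Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Compartmental digital-twin modelling of drug depletion in
    liver-on-chip and hepatocyte spheroid systems. Builds a three-compartment
    (media / interstitium / intracellular) linear ODE model from chip hardware
    geometry and compound physicochemistry, solves it analytically by
    eigendecomposition (with a stiff numerical fallback), estimates intrinsic
    on-chip clearance by Nelder-Mead minimisation of a relative-residual cost
    with an unbound intracellular-to-media partitioning (Kp_uu) anchor, and
    scales the result to human hepatic clearance through hepatocellularity
    scale-up and the well-stirred liver model. Includes local and Sobol global
    sensitivity analysis, a library of chip hardware presets, a seeded
    synthetic-data generator for end-to-end validation, and a conventional
    one-compartment comparator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    graphics,
    jsonlite,
    lhs,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
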