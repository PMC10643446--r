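Package: CoInPath
Title: Surface-Hopping Dynamics and Relaxation-Pathway Analysis for
    Non-Radiative Excited-State Decay
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for diagnosing non-radiative S1 to S0 decay through
    conical intersections in molecular model systems. Implements
    decoherence-corrected fewest-switches trajectory surface hopping on
    analytic two-state diabatic models (including a carbonyl-lock family
    in which a tunable stiffness suppresses the gap-closing stretch), an
    exact split-operator wavepacket propagator used as an independent
    benchmark, a data-driven extraction of the S1 to S0 relaxation
    coordinate from trajectory swarms via a gap-weighted fluctuation
    estimator, internal-coordinate geometry kernels (distances,
    proton-transfer coordinates, improper dihedrals, Kabsch
    superposition), and ensemble statistics over trajectory swarms
    (decay fractions, conical-intersection frame extraction,
    constrained-dynamics variance hierarchies, and standardized
    excited-state/crossing separation statistics).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
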