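Package: steerfield
Title: Current-Fraction Optimization for Multi-Contact Neurostimulation Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analytic optimization of current fractions across multi-contact
    electrode arrays for targeted neurostimulation (e.g. spinal cord
    stimulation). Builds unit-current basis fields from an anisotropic
    point-source volume-conductor model or from imported field tables,
    maximizes an excitation field (electric field or activating function)
    over regions of interest with the Lagrange-multiplier method using
    smooth-maximum and smooth-absolute-value surrogates, solves the
    resulting stationarity systems by multistart damped Newton iteration
    with analytic Jacobians, classifies critical points with bordered
    Hessians, and traces Pareto fronts between regions of interest and
    regions of avoidance with the epsilon-constraint method under full
    Karush-Kuhn-Tucker validation. Includes bipolar and random baseline
    configuration generators and a small command-line workbench.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lhs,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
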