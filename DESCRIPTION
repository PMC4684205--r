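Package: plesioswim
Title: Coupled Fluid and Articulated-Body Simulation of Four-Flippered
    Underwater Flight
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates a neutrally buoyant four-flippered swimmer (a
    plesiosaur-proportioned body built procedurally) in a grid-based
    incompressible Euler fluid.  The articulated body is driven through a
    26-parameter periodic stroke model by Stable-PD joint controllers, and
    body and fluid are coupled through a single variational pressure solve
    on volume-fraction weighted stencils.  A CMA-ES optimizer searches the
    stroke space for gaits that maximize straight forward travel under
    narrow, medium and wide joint-range presets, separately for all-limb,
    forelimb-only and hindlimb-only propulsion.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    parallel
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
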