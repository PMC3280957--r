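Package: phyllonoise
Title: Stochastic Inhibitory-Field Simulation and Defect Analysis of
    Spiral Phyllotaxis
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Event-driven simulation of the Douady-Couder inhibitory-field
    model of phyllotaxis on a conical shoot apex, with Gaussian noise on
    the initiation threshold or on the radius of the competent circle,
    optional secondary (co-inhibitory or age-correcting) fields, and a
    time-varying inhibition-range protocol.  Includes analysis of
    divergence-angle and plastochron sequences: detection of M-shaped
    permutation motifs, transient distichous angles, handedness
    reversals and concomitant initiations; contact-parastichy
    estimation; and seeded parameter-sweep drivers that tabulate defect
    proportions as a function of noise strength.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE, load = "source")
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
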