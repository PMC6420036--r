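Package: plasmidseg
Title: Evolutionarily Stable Segregation Strategies for High-Copy Plasmids
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Copy-number-structured population model for bacteria carrying a
    high-copy plasmid that confers antibiotic resistance at a metabolic cost.
    Builds the master-equation generator of the plasmid-bearing subpopulation
    with binomial segregation at division, computes long-term growth rates
    (spectral bounds / Lyapunov exponents) and stationary copy-number
    distributions, finds evolutionarily stable segregation strategies by
    projected steepest ascent on the dominant eigenvalue, evaluates a
    closed-form two-generation conceptual model, and simulates single-cell
    lineages with division records and fluorescence proxies emulating
    time-lapse microscopy analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
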