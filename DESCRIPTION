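Package: gjcolony
Title: Agent-Based Simulation of Gap-Junction-Mediated Differentiation
    Patterning in Stem-Cell Colonies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Off-lattice agent-based model of growing, dividing and
    differentiating embryonic stem-cell colonies in which a small
    pro-differentiation molecule diffuses between contacting cells through
    gap junctions whose permeability is modulated by cell-cycle phase and
    phenotype. Includes the per-hour fate rules combining a threshold-count
    Hill probability with an oscillatory stochastic term, in-silico
    perturbations of production rate and global permeability, a
    spatial-pattern classification pipeline (synthetic pattern-class
    training set, seven colony network metrics, PCA latent space and
    trajectory averaging), and exponential fitting of GAP-FRAP recovery
    traces.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    minpack.lm,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
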