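Package: codonkinetics
Title: Codon Usage, mRNA Structure and Ribosome-Profiling Translation Kinetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for comparing synonymous coding-sequence variants (for
    example a wild-type gene and its codon-optimized recoding) at the level
    of codon usage, mRNA secondary structure, and translation kinetics
    measured by ribosome profiling. Computes codon-usage statistics (CAI,
    RSCU, RSCPU), GC composition and sequence divergence; minimum-free-energy
    structures and equilibrium base-pairing probabilities with a
    self-contained folding engine plus an adapter for an external
    thermodynamic folder; per-codon A-site ribosome occupancy, RPKM and
    translation efficiency from aligned fragments; a Box-Cox / lagged
    stepwise-AIC regression explaining occupancy; and a cumulative-sum
    Kolmogorov-Smirnov procedure that detects regional divergence in
    translation kinetics. A synthetic-data generator with known ground truth
    makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    tidyr,
    tibble,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    withr,
    stats,
    utils,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Rsamtools,
    MASS
Config/testthat/edition: 3
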