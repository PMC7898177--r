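Package: emonorm
Title: Emotion-Based Social Norms in the Iterated Prisoner's Dilemma
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computational machinery for studying how emotion expressions,
    zero-determinant strategies, and reputation priors jointly shape
    cooperation and reputation updating in the iterated prisoner's dilemma.
    Provides memory-one strategy mathematics (transition matrices, stationary
    analysis, Press-Dyson determinants, zero-determinant certification with
    extortion/generous classification), outcome-conditioned emotion display
    policies, a synthetic-participant simulator for a 3x2x3 between-subjects
    factorial design, the associated statistical pipeline (Type III factorial
    ANOVA with partial eta-squared, Bonferroni pairwise post-hocs, one-sample
    t-tests), and derivation of emotion-based social-norm tables from
    behavioral data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    car,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
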