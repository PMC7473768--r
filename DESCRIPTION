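Package: cyclodom
Title: Emergence of Cyclic Dominance in Evolving Lotka-Volterra Communities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Individual-based eco-evolutionary simulation of a competitive
    Lotka-Volterra community in which novel types arise by mutation and
    inherit their parent's payoffs plus Gaussian noise. Provides an exact
    Gillespie simulator with a dynamically growing payoff matrix, pairwise
    stability classification (dominance, bistability, coexistence) and its
    deterministic ODE oracle, interaction-network triplet statistics
    including the fraction chi of cyclic dominance among dominance triplets,
    triplet lifespan tracking, trait-vector similarity analysis, exact and
    Monte-Carlo baselines for chi under random networks and random payoff
    matrices, and genealogy-conditioned payoff sampling to quantify how the
    genealogical structure of a triplet promotes or suppresses cyclic
    dominance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    deSolve,
    jsonlite,
    ape,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
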