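# cyclodom

Why is rock–paper–scissors competition so rare in nature? `cyclodom` is an
R package for studying how **cyclic dominance** (intransitive triplets, in
which each type beats exactly one other) emerges — or mostly fails to
emerge — in an evolving community where new types arise continually by
mutation.

The model couples evolutionary game theory to competitive Lotka–Volterra
dynamics. Individuals of type *i* are born at rate λ_b (a birth is a
mutant with probability μ), die at background rate λ_d, and die from
competition with a *j* individual at rate

    d_ij = α + exp(−A_ij),

where `A_ij` is the payoff of *i* against *j* and α > 0 bounds the
population. A mutant inherits its parent's payoff row and column plus
independent Gaussian noise of standard deviation σ (`A_i'j = A_ij + ξ`).
Pairs of types are classified from the sign pattern of
`(A_ii − A_ji, A_ij − A_jj)` into dominance, bistability, or coexistence;
triplets whose three links are all dominance are either **cyclic** or
**non-cyclic** (transitive), and the headline statistic is

    χ = (# cyclic) / (# cyclic + # non-cyclic),

the fraction of cyclic triplets among dominance triplets.

The package provides, as separate composable layers:

- an exact Gillespie simulator with a dynamically growing payoff matrix,
  per-mutation-event snapshots and a full genealogy log
  (`simulate_population()`, compiled core);
- the pairwise classifier and its independent ODE oracle
  (`classify_pair()`, `two_type_outcome_by_ode()` via deSolve);
- interaction-network and triplet statistics: `build_network()`,
  `count_triplets()`, `chi()`, lifespan tracking (`track_lifespans()`,
  `lifespan_ccdf()`), trait-vector similarity (`triplet_similarity_stats()`);
- exact and Monte-Carlo baselines: random link network (χ = 1/4 from 2
  cyclic vs 6 transitive configurations), i.i.d. random payoff matrix
  (χ = 1/13 by exact 216-ordering enumeration), and a mutant joining an
  uncorrelated pair (χ ≈ 0.02);
- genealogy-conditioned analysis: reduce a 3-leaf genealogy to five branch
  mutation counts (`extract_genealogy()`, `genealogy_triplet()`), sample
  payoff matrices conditioned on it (`sample_matrix_given_genealogy()`,
  exact covariance via `genealogy_entry_covariance()`), estimate
  χ(genealogy) (`chi_given_genealogy()`), and search for the genealogies
  that minimize or maximize χ (`search_extreme_chi()`: the maximizer
  approaches 1/6, the minimizer falls below 10⁻³);
- ensemble orchestration and structured export: `run_ensemble()`,
  `alpha_sweep()`, `export_run()` (CSV + JSON + Newick genealogies), and a
  thin command-line front end in `inst/cli/cyclodom.R`.

## Worked example

```r
library(cyclodom)

# Reference fractions of cyclic dominance
chi_random_network()
#> random_network: chi = 0.25  [exact-enumeration, n = 64]
chi_random_matrix_exact()
#> random_matrix_exact: chi = 0.0769231  [exact-enumeration, n = 216]
set.seed(1)
chi_mutant_from_pair(2e5)
#> mutant_from_pair: chi = 0.019809 (se 0.00077)  [monte-carlo, n = 2e+05]

# Evolve a community at a desk-scale parameter set (N ~ 500)
sim <- simulate_population(model_params(alpha = 1e-3, mu = 1e-3),
                           t_mut_max = 300, seed = 7)
sim
#> cyclodom_sim: 300 mutation events, 553546 reactions
#>   final: N = 416, n = 3 types; wall time T = 686.4

ts <- triplet_series(sim)         # per-mutation-event N, n, motif counts, chi
rec <- track_lifespans(sim)       # triplet lifespans in mutation events

# How does the genealogy of a triplet shape its chance of being cyclic?
g <- genealogy_triplet(w1 = 0, w2 = 1000, x = 1, y = 1, z = 1)  # late mutations
set.seed(2)
chi_given_genealogy(g, n_samples = 1e5)$chi
#> [1] 0.1593376
```

The three reference fractions order the story: links drawn blindly at
random would give χ = 0.25; independent random payoffs already couple the
links through the shared self-payoffs and give 1/13 ≈ 0.077; payoff
*inheritance* couples them much harder (χ ≈ 0.02 for a mutant joining a
pair), and a genealogy with most mutations accumulated before the last
divergence suppresses cycles almost completely. Evolved communities live
near that minimizer regime, which is why cyclic dominance is rare even
when mutation constantly supplies new candidate types.

The methods vignette (`vignettes/cyclic-dominance.Rmd`) documents the
model assumptions, the genealogy covariance construction, numerical
tolerances, and which full-scale results are out of desk-scale reach.

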