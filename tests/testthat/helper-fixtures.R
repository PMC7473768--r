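# Shared fixtures and independent oracles for the test suite.

# Hand-derived closed-form covariance of the nine payoff entries implied by
# a genealogy (w1, w2, x, y, z) with sigma = 1. Derived by accumulating the
# independent unit-variance noise increments entry by entry:
#   - every mutation on a lineage adds 1 to the variance of each entry in
#     that lineage's row and column;
#   - entries copied at a divergence inherit the parent entry's history,
#     which creates the shared (pre-divergence) components:
#     the j/k block shares the stem history x, and the i-row (resp. i-column)
#     entries against j and k share the pre-divergence history w1 + x.
# Entry order: column-major of the (i, j, k) matrix.
closed_form_genealogy_cov <- function(w1, w2, x, y, z) {
  nm <- c("i,i", "j,i", "k,i", "i,j", "j,j", "k,j", "i,k", "j,k", "k,k")
  S <- matrix(0, 9, 9, dimnames = list(nm, nm))
  diag(S) <- c(w1 + w2,
               w1 + x + w2 + y,
               w1 + x + w2 + z,
               w1 + x + w2 + y,
               x + y,
               x + y + z,
               w1 + x + w2 + z,
               x + y + z,
               x + z)
  jkblock <- c("j,j", "k,k", "j,k", "k,j")
  for (p in jkblock) for (q in jkblock) if (p != q) S[p, q] <- x
  S["i,j", "i,k"] <- S["i,k", "i,j"] <- w1 + x
  S["j,i", "k,i"] <- S["k,i", "j,i"] <- w1 + x
  S
}

# Reference 3x3 matrices with known triplet classes (no ties).
fixture_cyclic <- matrix(c(3, 5, 0,
                           1, 4, 6,
                           4, 2, 5), 3, 3, byrow = TRUE)
fixture_noncyclic <- matrix(c(5, 5.5, 5.2,
                              1, 4, 6,
                              1, 2, 3), 3, 3, byrow = TRUE)  # source 1, sink 3
fixture_mixed <- matrix(c(1, 2, 0,
                          2, 1, 6,
                          4, 2, 5), 3, 3, byrow = TRUE)      # pair (1,2) coexists

# Snapshot sequence for lifespan tracking: a non-cyclic triplet for
# t = 1..4, a class flip to cyclic at t = 5..9, then extinction of type 2
# at t = 10.
fixture_snapshots <- local({
  ids3 <- list(0:2)
  A <- c(rep(list(fixture_noncyclic), 4), rep(list(fixture_cyclic), 5),
         list(fixture_cyclic[c(1, 3), c(1, 3)]))
  list(t_mut = 1:10,
       ids = c(rep(ids3, 9), list(c(0L, 2L))),
       A = A)
})

# tiny genealogy logs with known branch counts
fixture_log_chain <- data.frame(t_mut = 1:2, parent = c(0L, 1L), child = c(1L, 2L))
fixture_log_star <- data.frame(t_mut = 1:2, parent = c(0L, 0L), child = c(1L, 2L))
fixture_log_extinct_intermediaries <- data.frame(
  t_mut = 1:5, parent = c(0L, 1L, 2L, 0L, 4L), child = c(1L, 2L, 3L, 4L, 5L))

random_payoff_matrix <- function(n, mean = 0, sd = 1) {
  payoff_matrix(matrix(rnorm(n * n, mean, sd), n, n))
}
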