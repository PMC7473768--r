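test_that("Fl is the post-divergence mutation fraction", {
  expect_equal(fl(genealogy_triplet(3, 1, 2, 4, 5)), 10 / 15)
  expect_equal(fl(genealogy_triplet(0, 5, 1, 2, 3)), 10 / 11)
  expect_equal(fl(genealogy_triplet(2, 0, 3, 1, 0)), 1 / 6)
  # label symmetry j <-> k
  expect_equal(fl(genealogy_triplet(2, 1, 3, 4, 7)),
               fl(genealogy_triplet(2, 1, 3, 7, 4)))
})

test_that("impossible genealogies are rejected", {
  expect_error(genealogy_triplet(0, 5, 0, 1, 1), "w1 \\+ x")
  expect_error(genealogy_triplet(1, 1, 1, 0, 0), "y \\+ z")
  expect_error(genealogy_triplet(-1, 1, 1, 1, 1), "non-negative")
  expect_error(genealogy_triplet(0.5, 1, 1, 1, 1), "non-negative")
  # leaves must be distinct: i = o and j = n with no separating mutations
  expect_error(genealogy_triplet(0, 0, 1, 0, 1), NA) # valid: i=o, j=n, k 1 off
  expect_error(genealogy_triplet(1, 0, 0, 0, 1), NA) # valid
})

test_that("the entry covariance matches the hand-derived closed form", {
  for (cfg in list(c(2, 3, 1, 2, 4), c(0, 2, 1, 1, 3), c(1, 0, 2, 0, 3),
                   c(5, 0, 0, 1, 1), c(1, 0, 100, 1, 1), c(0, 50, 1, 1, 1))) {
    g <- genealogy_triplet(cfg[1], cfg[2], cfg[3], cfg[4], cfg[5])
    S <- genealogy_entry_covariance(g)
    S0 <- closed_form_genealogy_cov(cfg[1], cfg[2], cfg[3], cfg[4], cfg[5])
    expect_equal(S, S0[rownames(S), colnames(S)],
                 info = paste(cfg, collapse = ","))
  }
  # sigma enters as a pure scale factor
  g <- genealogy_triplet(2, 3, 1, 2, 4)
  expect_equal(genealogy_entry_covariance(g, sigma = 2),
               4 * genealogy_entry_covariance(g, sigma = 1))
})

test_that("the replay sampler draws from the covariance-implied law", {
  set.seed(41)
  g <- genealogy_triplet(2, 3, 1, 2, 4)
  n <- 2e4
  M <- t(replicate(n, as.vector(sample_matrix_given_genealogy(g))))
  Sth <- genealogy_entry_covariance(g)
  se <- sqrt((outer(diag(Sth), diag(Sth)) + Sth^2) / n)
  z <- abs(cov(M) - Sth) / pmax(se, 1e-12)
  expect_lt(max(z), 5)           # 45 distinct covariance entries checked
  expect_true(all(abs(colMeans(M)) < 5 * sqrt(diag(Sth) / n)))
})

test_that("the sampled distribution is invariant to event order within segments", {
  set.seed(43)
  g <- genealogy_triplet(3, 2, 2, 2, 3)
  n <- 2e4
  M <- t(replicate(n, as.vector(sample_matrix_given_genealogy(g, shuffle_segments = TRUE))))
  Sth <- genealogy_entry_covariance(g)
  se <- sqrt((outer(diag(Sth), diag(Sth)) + Sth^2) / n)
  expect_lt(max(abs(cov(M) - Sth) / pmax(se, 1e-12)), 5)
})

test_that("chi given a genealogy is sigma-invariant and Fl-monotone", {
  g <- genealogy_triplet(1, 10, 4, 3, 2)
  set.seed(51)
  c1 <- chi_given_genealogy(g, sigma = 1, n_samples = 4e4)
  c3 <- chi_given_genealogy(g, sigma = 3, n_samples = 4e4)
  expect_lt(abs(c1$chi - c3$chi), 3 * sqrt(c1$se^2 + c3$se^2))
  # more post-divergence mutations at fixed total -> larger chi
  total <- 40
  chis <- vapply(c(4, 20, 36), function(post) {
    gg <- genealogy_triplet(w1 = 1, w2 = post - 2, x = total - post - 1,
                            y = 1, z = 1)
    set.seed(52)
    chi_given_genealogy(gg, n_samples = 6e4)$chi
  }, numeric(1))
  expect_true(all(diff(chis) > 0))
})

test_that("genealogies extracted from logs have the expected branch counts", {
  # chain 0 -> 1 -> 2: close pair (1, 2), i = 0 = root
  g <- extract_genealogy(fixture_log_chain, c(0, 1, 2))
  expect_equal(c(g$w1, g$w2, g$x, g$y, g$z), c(0, 0, 1, 0, 1))
  lv <- attr(g, "leaves")
  expect_identical(unname(lv["i"]), 0L)
  # star: 0 spawns 1 then 2; lineage of 1 splits first, so i = 1
  g <- extract_genealogy(fixture_log_star, c(0, 1, 2))
  expect_equal(c(g$w1, g$w2, g$x, g$y, g$z), c(1, 0, 0, 0, 1))
  expect_identical(unname(attr(g, "leaves")["i"]), 1L)
  # extinct intermediaries on i's lineage count toward w1/w2 by timing
  g <- extract_genealogy(fixture_log_extinct_intermediaries, c(3, 5, 0))
  expect_equal(c(g$w1, g$w2, g$x, g$y, g$z), c(3, 0, 0, 2, 0))
  expect_identical(unname(attr(g, "leaves")["i"]), 3L)
  expect_equal(fl(g), 2 / 5)
  expect_error(extract_genealogy(fixture_log_chain, c(0, 1, 9)), "missing")
})

test_that("extraction agrees with simulation and the two chi routes are consistent", {
  p <- model_params(alpha = 1e-3, mu = 3e-3)
  sim <- simulate_population(p, t_mut_max = 500, seed = 61)
  s <- sim$snapshots
  r <- which(s$n >= 3)
  expect_gt(length(r), 0)
  r <- r[length(r)]
  ids <- s$ids[[r]]
  g <- extract_genealogy(sim$genealogy, ids[1:3])
  expect_s3_class(g, "genealogy_triplet")
  # all counts consistent with the number of recorded mutation events
  expect_lte(g$w1 + g$w2 + g$x + g$y + g$z, nrow(sim$genealogy))
  expect_gte(fl(g), 0); expect_lte(fl(g), 1)
})

test_that("genealogies round-trip through Newick plus sidecar", {
  g <- genealogy_triplet(3, 1, 2, 4, 5)
  path <- tempfile(fileext = ".nwk")
  write_genealogy(g, path)
  g2 <- read_genealogy(path)
  expect_equal(g2[c("w1", "w2", "x", "y", "z")], g[c("w1", "w2", "x", "y", "z")])
  tree <- ape::read.tree(path)
  expect_setequal(tree$tip.label, c("i", "j", "k"))
  expect_setequal(tree$edge.length[tree$edge[, 2] <= 3], c(4, 4, 5))
  unlink(c(path, paste0(path, ".json")))
})

test_that("extreme-genealogy search brackets the random-matrix fraction", {
  set.seed(71)
  res_max <- search_extreme_chi("max", budget = 40, n_screen = 5e3, n_final = 4e4)
  res_min <- search_extreme_chi("min", budget = 40, n_screen = 5e3, n_final = 4e4)
  expect_gt(res_max$chi, 1 / 13)
  expect_lt(res_min$chi, 0.01)
  expect_gt(fl(res_max$genealogy), 0.9)   # maximizer: mutations after divergence
  expect_lt(fl(res_min$genealogy), 0.1)   # minimizer: mutations before divergence
})
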