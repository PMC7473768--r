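test_that("the network has one classified link per unordered pair", {
  m <- payoff_matrix(matrix(c(1, 0, 2, 0), 2, 2), 0:1) # A11=1>A21=2? no: check below
  # columns: A = [1 2; 0 0] column-major c(1,0,2,0): A11=1, A21=0, A12=2, A22=0
  net <- build_network(m)
  expect_identical(nrow(net$links), 1L)
  expect_identical(net$links$class, "dominance")
  expect_identical(net$links$winner, 0L)
  set.seed(3)
  m7 <- random_payoff_matrix(7)
  net7 <- build_network(m7)
  expect_equal(nrow(net7$links), choose(7, 2))
  # consistency with classify_pair on a few pairs
  for (k in c(1, 5, 11)) {
    i <- match(net7$links$a[k], m7$type_ids); j <- match(net7$links$b[k], m7$type_ids)
    pc <- classify_pair(m7$A[i, i], m7$A[i, j], m7$A[j, i], m7$A[j, j])
    expect_identical(net7$links$class[k] == "dominance", pc %in% c("dom_first", "dom_second"))
  }
  net3 <- build_network(payoff_matrix(fixture_cyclic))
  expect_identical(net3$links$class, rep("dominance", 3))
})

test_that("link-type proportions for random payoffs are (0.50, 0.25, 0.25)", {
  set.seed(19)
  n <- 4e4
  a11 <- rnorm(n); a12 <- rnorm(n); a21 <- rnorm(n); a22 <- rnorm(n)
  first_own <- a11 > a21; first_other <- a12 > a22
  dom <- first_own == first_other
  bis <- first_own & !first_other
  p <- c(mean(dom), mean(bis), mean(!dom & !bis))
  se <- sqrt(0.25 * 0.75 / n)
  expect_lt(abs(p[1] - 0.50), 3 * sqrt(0.5 * 0.5 / n))
  expect_lt(abs(p[2] - 0.25), 3 * se)
  expect_lt(abs(p[3] - 0.25), 3 * se)
  # the network-level helper agrees on a single link
  mcoex <- payoff_matrix(matrix(c(0, 1, 1, 0), 2, 2), 0:1)
  expect_equal(link_type_proportions(build_network(mcoex)),
               c(dominance = 0, bistability = 0, coexistence = 1))
  expect_equal(sum(link_type_proportions(build_network(random_payoff_matrix(6)))), 1)
})

test_that("triplet counts are conserved and chi follows its definition", {
  expect_equal(count_triplets(fixture_cyclic)$counts,
               c(cyclic = 1L, noncyclic = 0L, mixed = 0L))
  expect_equal(count_triplets(fixture_mixed)$counts[["mixed"]], 1L)
  set.seed(23)
  for (n in c(3, 5, 10)) {
    ct <- count_triplets(random_payoff_matrix(n))
    expect_equal(sum(ct$counts), choose(n, 3))
    expect_equal(sum(ct$proportions), 1)
  }
  ct2 <- count_triplets(random_payoff_matrix(2))
  expect_false(ct2$valid)
  expect_true(all(is.na(ct2$counts)))
  expect_equal(chi(c(cyclic = 1, noncyclic = 0)), 1)
  expect_equal(chi(c(cyclic = 0, noncyclic = 5)), 0)
  expect_equal(chi(c(cyclic = 2, noncyclic = 24)), 1 / 13)
  expect_true(is.na(chi(c(cyclic = 0, noncyclic = 0))))
})

test_that("lifespan records capture formation, destruction and cause", {
  rec <- track_lifespans(fixture_snapshots)
  rec <- rec[!rec$censored, ]
  non <- rec[rec$class == "noncyclic", ]
  cyc <- rec[rec$class == "cyclic", ]
  expect_identical(nrow(non), 1L)
  expect_identical(nrow(cyc), 1L)
  # the class flip at t = 5 closes the noncyclic record and opens a cyclic one
  expect_identical(c(non$t_formed, non$t_destroyed), c(1L, 5L))
  expect_identical(non$lifespan, 4L)
  expect_identical(non$cause, "link_flip")
  # extinction of a member at t = 10 closes the cyclic record
  expect_identical(c(cyc$t_formed, cyc$t_destroyed), c(5L, 10L))
  expect_identical(cyc$cause, "extinction")
  # unordered snapshots are rejected
  bad <- fixture_snapshots; bad$t_mut <- rev(bad$t_mut)
  expect_error(track_lifespans(bad), "ordered")
})

test_that("lifespan records partition each triplet's timeline", {
  p <- model_params(alpha = 1e-3, mu = 3e-3)
  sim <- simulate_population(p, t_mut_max = 600, seed = 12)
  rec <- track_lifespans(sim)
  if (nrow(rec)) {
    expect_true(all(rec$lifespan >= 0))
    for (kk in unique(rec$key)) {
      rk <- rec[rec$key == kk, ]
      rk <- rk[order(rk$t_formed), ]
      expect_true(all(rk$censored | rk$t_destroyed > rk$t_formed))
      if (nrow(rk) > 1) # no overlaps: each record closes before the next opens
        expect_true(all(rk$t_destroyed[-nrow(rk)] <= rk$t_formed[-1]))
    }
    # censored records are flagged, open at the end, and excluded from CCDFs
    expect_true(all(is.na(rec$t_destroyed[rec$censored])))
  }
})

test_that("the lifespan CCDF counts strict exceedances", {
  cc <- lifespan_ccdf(c(1, 1, 2))
  expect_equal(cc$ccdf[cc$x == -1], 1)
  expect_equal(cc$ccdf[cc$x == 0], 1)
  expect_equal(cc$ccdf[cc$x == 1], 1 / 3)
  expect_equal(cc$ccdf[cc$x == 2], 0)
  expect_true(all(diff(cc$ccdf) <= 0))
  cc1 <- lifespan_ccdf(3)
  expect_equal(cc1$ccdf, c(1, 1, 1, 1, 0))
})

test_that("cyclic and noncyclic lifespan distributions are close at steady state", {
  p <- model_params(alpha = 3e-4, mu = 1e-3)
  lsp <- list(cyclic = c(), noncyclic = c())
  for (r in 1:3) {
    sim <- simulate_population(p, t_mut_max = 1500, seed = 400 + r)
    if (sim$extinct) next
    rec <- track_lifespans(sim, window = c(750, 1500))
    rec <- rec[!rec$censored, ]
    for (cl in names(lsp)) lsp[[cl]] <- c(lsp[[cl]], rec$lifespan[rec$class == cl])
  }
  expect_gt(length(lsp$cyclic), 10)
  expect_gt(length(lsp$noncyclic), 10)
  # overlapping interquartile ranges: the two motifs live about equally long
  qc <- quantile(lsp$cyclic, c(0.25, 0.75))
  qn <- quantile(lsp$noncyclic, c(0.25, 0.75))
  expect_true(qc[1] <= qn[2] && qn[1] <= qc[2])
})
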