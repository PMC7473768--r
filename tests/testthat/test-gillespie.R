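test_that("the initial state sits at the deterministic one-type equilibrium", {
  p <- model_params(alpha = 5e-6, mu = 1e-5)
  set.seed(1)
  st <- initial_state(p, init_sd = 0)          # founder payoff exactly ln(1000)
  expect_identical(length(st$x), 1L)
  expect_identical(st$t_mut, 0L)
  expect_equal(unname(st$x), round(0.5 / 0.001005))   # 498
  set.seed(42); s1 <- initial_state(p)
  set.seed(42); s2 <- initial_state(p)
  expect_identical(s1, s2)
  expect_error(model_params(lambda_b = 0.3, lambda_d = 0.4), "exceed")
})

test_that("the rate table implements the reaction rules", {
  p <- model_params(alpha = 1e-3, mu = 1e-2)
  st <- initial_state(p, initial_abundance = 2, init_sd = 0)
  r <- event_rates(st, p)
  d11 <- competition_death_rate(log(1000), p$alpha)
  expect_equal(r$birth, p$lambda_b * 2)
  expect_equal(r$bg_death, p$lambda_d * 2)
  # same-type competition counts ordered pairs of distinct individuals
  expect_equal(r$competition, 2 * 1 * d11)
  # multi-type: birth rates sum to lambda_b * N exactly
  set.seed(4)
  st$m <- mutate_payoffs(st$m, 0L, 1)
  st$x <- c(st$x, "1" = 3)
  r2 <- event_rates(st, p)
  expect_equal(sum(r2$birth), p$lambda_b * 5)
  d <- matrix(competition_death_rate(st$m$A, p$alpha), 2, 2)
  expect_equal(r2$competition,
               c(2 * (2 - 1) * d[1, 1] + 2 * 3 * d[1, 2],
                 3 * (3 - 1) * d[2, 2] + 3 * 2 * d[2, 1]))
})

test_that("single steps respect the mutation probability limits", {
  p0 <- model_params(alpha = 1e-2, mu = 0)
  set.seed(8)
  st <- initial_state(p0)
  for (k in 1:50) st <- sim_step(st, p0)
  expect_identical(st$t_mut, 0L)               # mu = 0: the clock never advances
  expect_identical(nrow(st$genealogy), 0L)
  p1 <- model_params(alpha = 1e-2, mu = 1)
  set.seed(8)
  st <- initial_state(p1)
  births0 <- 0
  for (k in 1:50) {
    n_before <- sum(st$x)
    st <- sim_step(st, p1)
    if (sum(st$x) > n_before) births0 <- births0 + 1
  }
  expect_identical(st$t_mut, as.integer(births0))  # mu = 1: every birth mutates
  expect_identical(nrow(st$genealogy), st$t_mut)
})

test_that("runs are reproducible and snapshot bookkeeping is exact", {
  p <- model_params(alpha = 1e-2, mu = 1e-2)
  s1 <- simulate_population(p, t_mut_max = 50, seed = 5)
  s2 <- simulate_population(p, t_mut_max = 50, seed = 5)
  expect_identical(s1$snapshots, s2$snapshots)
  expect_identical(s1$final, s2$final)
  expect_identical(s1$genealogy, s2$genealogy)
  if (!s1$extinct) {
    expect_identical(s1$snapshots$t_mut, 1:50)
    expect_identical(s1$t_mut, 50L)
    # every snapshot's ids match its matrix dimension; N positive
    for (r in seq_along(s1$snapshots$t_mut)) {
      expect_identical(length(s1$snapshots$ids[[r]]), nrow(s1$snapshots$A[[r]]))
      expect_identical(s1$snapshots$n[r], length(s1$snapshots$ids[[r]]))
    }
    # each child appears exactly once in the genealogy log
    expect_false(anyDuplicated(s1$genealogy$child) > 0)
  }
})

test_that("the stochastic drift of N matches the deterministic LV rate", {
  # one type, x0 = 400 above the equilibrium 1 + 0.5/d11 ~ 250:
  # E[dN/dT] = lv_rhs up to the O(1) distinct-pairs correction
  p <- model_params(alpha = 1e-3, mu = 0)
  d11 <- competition_death_rate(log(1000), p$alpha)
  horizon <- 0.05
  set.seed(31)
  drifts <- replicate(200, {
    sim <- simulate_population(p, t_mut_max = 1, initial_abundance = 400,
                               init_sd = 0, max_events = 1e4, trace_thin = 1)
    tr <- sim$trace
    row <- which(tr$T >= horizon)[1]
    (tr$N[row] - 400) / tr$T[row]
  })
  expected <- 0.5 * 400 - d11 * 400 * 399
  se <- sd(drifts) / sqrt(length(drifts))
  expect_lt(abs(mean(drifts) - expected), 4 * se)
})

test_that("extinction is flagged, not raised, and small runs stay fast", {
  # invasion from a single founder: survival is a branching-process coin
  # flip with extinction probability near lambda_d / lambda_b
  p <- model_params(alpha = 1e-3, mu = 1e-2)
  set.seed(77)
  ext <- vapply(1:20, function(r)
    simulate_population(p, t_mut_max = 30, seed = 1000 + r,
                        initial_abundance = 1, max_events = 2e5)$extinct,
    logical(1))
  expect_true(any(ext))         # survival fraction strictly between 0 and 1
  expect_true(!all(ext))
  sim <- simulate_population(model_params(alpha = 1e-2, mu = 1e-2),
                             t_mut_max = 50, seed = 2)
  expect_true(sim$extinct || length(sim$snapshots$t_mut) == 50L)
})
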