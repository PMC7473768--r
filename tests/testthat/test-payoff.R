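test_that("competition death rate follows alpha + exp(-A)", {
  expect_equal(competition_death_rate(0, 5e-6), 1.000005)
  expect_equal(competition_death_rate(log(1000), 5e-6), 0.001005)
  # clamped limit: the rate floors at alpha instead of underflowing
  expect_equal(competition_death_rate(1e6, 5e-6), 5e-6)
  expect_gt(competition_death_rate(10, 1e-3), 1e-3)
  # monotonically decreasing in the payoff
  A <- sort(rnorm(50))
  expect_true(all(diff(competition_death_rate(A, 1e-3)) <= 0))
  expect_error(competition_death_rate(NaN, 1e-3), "finite")
  expect_error(competition_death_rate(0, -1), "positive")
})

test_that("pairwise classification matches the four sign scenarios", {
  expect_identical(classify_pair(1, 2, 0, 0), "dom_first")
  expect_identical(classify_pair(0, 0, 1, 2), "dom_second")
  expect_identical(classify_pair(1, 0, 0, 1), "bistable")
  expect_identical(classify_pair(0, 1, 1, 0), "coexist")
  expect_error(classify_pair(1, 2, 1, 0), "tie")
  expect_error(classify_pair(1, 2, 0, 2), "tie")
})

test_that("pairwise classification is antisymmetric under type swap", {
  set.seed(11)
  swap_map <- c(dom_first = "dom_second", dom_second = "dom_first",
                bistable = "bistable", coexist = "coexist")
  for (r in 1:200) {
    A <- rnorm(4) # Aii, Aij, Aji, Ajj
    fwd <- classify_pair(A[1], A[2], A[3], A[4])
    rev <- classify_pair(A[4], A[3], A[2], A[1]) # j first
    expect_identical(rev, unname(swap_map[fwd]))
  }
})

test_that("triplet classification identifies cyclic, noncyclic, mixed", {
  cl <- classify_triplet(fixture_cyclic)
  expect_identical(cl$class, "cyclic")
  expect_identical(cl$orientation, 1L) # 1 beats 2 beats 3 beats 1
  cl <- classify_triplet(fixture_noncyclic)
  expect_identical(cl$class, "noncyclic")
  expect_identical(cl$source, 1L)
  expect_identical(cl$sink, 3L)
  expect_identical(classify_triplet(fixture_mixed)$class, "mixed")
})

test_that("triplet class is invariant under simultaneous row/column permutation", {
  set.seed(7)
  for (r in 1:100) {
    A <- matrix(rnorm(9), 3, 3)
    base <- classify_triplet(A)$class
    for (p in list(c(2, 1, 3), c(2, 3, 1), c(3, 2, 1), c(3, 1, 2), c(1, 3, 2))) {
      expect_identical(classify_triplet(A[p, p])$class, base)
    }
  }
})

test_that("triplet class depends only on the within-column orderings", {
  # build the 216-entry lookup from canonical rank-pattern matrices, then
  # check random matrices classify identically to their ordering pattern
  perms <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  key_of <- function(A) paste(apply(A, 2, function(col) paste(rank(col), collapse = "")),
                              collapse = "|")
  lookup <- new.env(parent = emptyenv())
  for (p1 in 1:6) for (p2 in 1:6) for (p3 in 1:6) {
    A <- cbind(perms[p1, ], perms[p2, ], perms[p3, ])
    assign(key_of(A), classify_triplet(A)$class, envir = lookup)
  }
  set.seed(21)
  n <- 1e4
  E <- matrix(rnorm(n * 9), ncol = 9)
  codes <- classify_triplets_bulk(E)
  for (r in seq_len(500)) { # scalar spot-check against the lookup
    A <- matrix(E[r, ], 3, 3)
    expect_identical(classify_triplet(A)$class, get(key_of(A), envir = lookup))
  }
  # and the bulk classifier agrees with the scalar one on the same rows
  scalar <- vapply(seq_len(500), function(r)
    classify_triplet(matrix(E[r, ], 3, 3))$class, character(1))
  expect_identical(c("mixed", "cyclic", "noncyclic")[codes[1:500] + 1L], scalar)
})

test_that("mutation appends one type and leaves the old block untouched", {
  set.seed(3)
  m <- random_payoff_matrix(4)
  m2 <- mutate_payoffs(m, parent_id = 2L, sigma = 1)
  expect_identical(dim(m2$A), c(5L, 5L))
  expect_identical(m2$type_ids, c(m$type_ids, 4L))
  expect_identical(m2$A[1:4, 1:4], m$A)          # bit-identical old block
  expect_error(mutate_payoffs(m, 99L, 1), "unknown parent")
  # zero-noise limit: a 1x1 matrix duplicates exactly
  m1 <- payoff_matrix(matrix(2.5), 0L)
  m1b <- mutate_payoffs(m1, 0L, sigma = 0)
  expect_equal(unname(m1b$A), matrix(2.5, 2, 2))
})

test_that("mutation noise has the right moments and is independent per entry", {
  set.seed(5)
  m <- payoff_matrix(matrix(c(0, 0, 0, 0), 2, 2), 0:1)
  n <- 2e4
  draws <- matrix(NA_real_, n, 5)
  for (r in seq_len(n)) {
    mm <- mutate_payoffs(m, 0L, sigma = 1.5)
    draws[r, ] <- c(mm$A[3, 1], mm$A[3, 2], mm$A[1, 3], mm$A[2, 3], mm$A[3, 3])
  }
  expect_true(all(abs(colMeans(draws)) < 4 * 1.5 / sqrt(n)))
  expect_true(all(abs(apply(draws, 2, var) - 2.25) < 0.1))
  cors <- cor(draws)[lower.tri(diag(5))]
  expect_true(all(abs(cors) < 4 / sqrt(n)))
})

test_that("type removal keeps surviving entries bit-identical and never reuses IDs", {
  set.seed(9)
  m <- random_payoff_matrix(3)
  expect_identical(remove_types(m, integer(0)), m)
  m2 <- remove_types(m, 1L)
  expect_identical(m2$type_ids, c(0L, 2L))
  expect_identical(m2$A, m$A[c(1, 3), c(1, 3)])
  expect_error(remove_types(m, 7L), "non-extant")
  # remove then re-add: the new type gets a fresh ID, not the removed one
  m3 <- mutate_payoffs(m2, 0L, 1)
  expect_identical(m3$type_ids, c(0L, 2L, 3L))
  # removing everything flags the empty (extinct) matrix
  m0 <- remove_types(m, m$type_ids)
  expect_identical(nrow(m0$A), 0L)
  # mutate followed by removing the mutant is the identity
  m4 <- remove_types(mutate_payoffs(m, 2L, 1), 3L)
  expect_identical(m4$A, m$A)
  expect_identical(m4$type_ids, m$type_ids)
})

test_that("payoff CSV round trip preserves entries and IDs", {
  set.seed(13)
  m <- random_payoff_matrix(4)
  m <- remove_types(m, 1L)
  f <- tempfile(fileext = ".csv")
  write_payoff_csv(m, f)
  m2 <- read_payoff_csv(f)
  expect_identical(m2$type_ids, m$type_ids)
  expect_equal(unname(m2$A), unname(m$A))
  unlink(f)
})
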