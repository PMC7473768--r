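# Trait-vector similarity of triplet members. Each member l of a triplet
# {i, j, k} is summarized by the 6-entry vector
#   T_l = (A_li, A_lj, A_lk, A_il, A_jl, A_kl):
# its payoff row against the triplet and the others' payoff column against
# it. For l = i the self-payoff A_ii legitimately occupies two slots.

#' Trait vector of a triplet member
#'
#' @param m a [payoff_matrix()] (or plain matrix with implicit IDs
#'   `0:(n-1)`).
#' @param triplet integer vector of three extant type IDs.
#' @param l one member ID of `triplet`.
#' @return numeric vector of length 6, entries taken verbatim from the
#'   payoff matrix (no centering).
#' @export
trait_vector <- function(m, triplet, l) {
  if (!inherits(m, "payoff_matrix")) m <- payoff_matrix(as.matrix(m))
  triplet <- as.integer(triplet)
  if (length(triplet) != 3L || anyDuplicated(triplet)) stop("triplet must be three distinct IDs")
  if (!(l %in% triplet)) stop("l must be a member of the triplet")
  idx <- match(triplet, m$type_ids)
  if (anyNA(idx)) stop("triplet members must be extant")
  li <- match(as.integer(l), m$type_ids)
  unname(c(m$A[li, idx], m$A[idx, li]))
}

#' Shift and normalize the three trait vectors of a triplet
#'
#' A single shift constant — the mean of the 18 entries pooled across the
#' triplet's three trait vectors — is subtracted from every entry, then
#' each vector is scaled to unit norm. The single pooled shift makes the
#' similarity invariant to adding a global constant to all payoffs (the
#' average payoff grows without bound in the model, so raw scalar products
#' would be dominated by the mean level).
#'
#' @param vectors list of three length-6 trait vectors.
#' @param shift optional shift constant; defaults to the pooled mean of the
#'   18 entries. Supplying e.g. the whole population matrix mean switches
#'   the centering scope for sensitivity checks.
#' @return list of three unit vectors.
#' @export
center_and_normalize <- function(vectors, shift = NULL) {
  if (length(vectors) != 3L || !all(lengths(vectors) == 6L))
    stop("three length-6 vectors required")
  if (is.null(shift)) shift <- mean(unlist(vectors))
  lapply(vectors, function(v) {
    w <- v - shift
    nrm <- sqrt(sum(w^2))
    if (nrm == 0) stop("degenerate trait vector: all entries equal the pooled mean")
    w / nrm
  })
}

#' Similarity statistics of a triplet
#'
#' Computes the three pairwise scalar products of the centered, normalized
#' trait vectors and returns their mean and standard deviation. Larger
#' scalar products mean more similar types. The statistics are invariant
#' under relabeling of the triplet, under adding a constant to all
#' payoffs, and under scaling all payoffs by a positive constant.
#'
#' @inheritParams trait_vector
#' @param shift_scope `"triplet"` (default): center by the pooled mean of
#'   the triplet's 18 trait-vector entries; `"matrix"`: center by the mean
#'   of the whole payoff matrix (sensitivity alternative).
#' @return named numeric vector `c(mean, sd)`; `mean` lies in `[-1, 1]`.
#' @export
triplet_similarity_stats <- function(m, triplet,
                                     shift_scope = c("triplet", "matrix")) {
  shift_scope <- match.arg(shift_scope)
  if (!inherits(m, "payoff_matrix")) m <- payoff_matrix(as.matrix(m))
  vs <- lapply(triplet, function(l) trait_vector(m, triplet, l))
  u <- center_and_normalize(vs, shift = if (shift_scope == "matrix") mean(m$A))
  s <- c(sum(u[[1]] * u[[2]]), sum(u[[1]] * u[[3]]), sum(u[[2]] * u[[3]]))
  c(mean = mean(s), sd = sd(s))
}

#' Similarity statistics for all dominance triplets of a simulation window
#'
#' Scans the mutation-event snapshots of a run (optionally restricted to a
#' steady-state window), finds every cyclic and non-cyclic dominance
#' triplet, and records its similarity mean/sd at the snapshot where it is
#' observed. One row per (snapshot, triplet).
#'
#' @param sim a `cyclodom_sim`.
#' @param window optional `c(lo, hi)` on `t_mut`.
#' @param shift_scope see [triplet_similarity_stats()].
#' @return data.frame: `t_mut`, `class`, `mean`, `sd`.
#' @export
similarity_series <- function(sim, window = NULL,
                              shift_scope = c("triplet", "matrix")) {
  shift_scope <- match.arg(shift_scope)
  stopifnot(inherits(sim, "cyclodom_sim"))
  s <- sim$snapshots
  keep <- if (is.null(window)) seq_along(s$t_mut) else
    which(s$t_mut >= window[1] & s$t_mut <= window[2])
  rows <- list()
  for (r in keep) {
    if (s$n[r] < 3L) next
    A <- s$A[[r]]; ids <- s$ids[[r]]
    tt <- triplet_table(A, ids)
    tt <- tt[tt$code != 0L, , drop = FALSE]
    for (q in seq_len(nrow(tt))) {
      trip <- c(tt$a[q], tt$b[q], tt$c[q])
      st <- triplet_similarity_stats(payoff_matrix(A, ids), trip, shift_scope)
      rows[[length(rows) + 1L]] <- data.frame(
        t_mut = s$t_mut[r],
        class = if (tt$code[q] == 1L) "cyclic" else "noncyclic",
        mean = st[["mean"]], sd = st[["sd"]])
    }
  }
  if (!length(rows))
    return(data.frame(t_mut = integer(), class = character(),
                      mean = numeric(), sd = numeric()))
  do.call(rbind, rows)
}

#' Similarity reference cloud for random payoff matrices
#'
#' Draws i.i.d. standard-normal 3x3 matrices, classifies them, and returns
#' the similarity mean/sd of each — the uncorrelated-assembly reference
#' against which simulated (inherited-payoff) triplets are compared.
#'
#' @param n_samples number of random matrices.
#' @return data.frame: `class` ("cyclic", "noncyclic" or "mixed"), `mean`,
#'   `sd`.
#' @export
similarity_random_reference <- function(n_samples) {
  E <- matrix(rnorm(n_samples * 9), ncol = 9)
  codes <- classify_triplets_bulk(E)
  res <- data.frame(class = c("mixed", "cyclic", "noncyclic")[codes + 1L],
                    mean = NA_real_, sd = NA_real_)
  for (r in seq_len(n_samples)) {
    st <- triplet_similarity_stats(matrix(E[r, ], 3, 3), c(0L, 1L, 2L))
    res$mean[r] <- st[["mean"]]; res$sd[r] <- st[["sd"]]
  }
  res
}
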