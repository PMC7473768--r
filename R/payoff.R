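#' Payoff matrix for an evolving community
#'
#' A `payoff_matrix` holds the square matrix of interaction payoffs
#' `A[i, j]` — the payoff an individual of type `i` obtains from an
#' interaction with an individual of type `j` — together with the persistent
#' integer identifiers of the extant types. Type IDs are never reused within
#' a run: when a mutant arises it gets a fresh ID, and extinct types are
#' dropped without renumbering the survivors.
#'
#' @param A square numeric matrix of payoffs (finite entries).
#' @param type_ids integer vector of unique non-negative type IDs, one per
#'   row/column of `A`. Defaults to `0:(n-1)`.
#' @param next_id smallest ID guaranteed never to have been used; defaults
#'   to `max(type_ids) + 1`.
#' @return An object of class `payoff_matrix`.
#' @examples
#' m <- payoff_matrix(matrix(c(3, 1, 4, 5, 4, 2, 0, 6, 5), 3, 3, byrow = TRUE))
#' classify_triplet(m$A)
#' @export
payoff_matrix <- function(A, type_ids = NULL, next_id = NULL) {
  A <- as.matrix(A)
  if (nrow(A) != ncol(A)) stop("payoff matrix must be square")
  if (nrow(A) > 0 && !all(is.finite(A))) stop("payoff entries must be finite")
  if (is.null(type_ids)) type_ids <- seq_len(nrow(A)) - 1L
  type_ids <- as.integer(type_ids)
  if (length(type_ids) != nrow(A)) stop("one type ID per matrix row required")
  if (anyDuplicated(type_ids)) stop("type IDs must be unique")
  if (length(type_ids) > 0 && any(type_ids < 0L)) stop("type IDs must be non-negative")
  if (is.null(next_id)) next_id <- if (length(type_ids)) max(type_ids) + 1L else 0L
  dimnames(A) <- list(type_ids, type_ids)
  structure(list(A = A, type_ids = type_ids, next_id = as.integer(next_id)),
            class = "payoff_matrix")
}

#' @export
print.payoff_matrix <- function(x, ...) {
  cat(sprintf("payoff_matrix: %d extant type(s)\n", length(x$type_ids)))
  if (length(x$type_ids)) print(round(x$A, 4))
  invisible(x)
}

#' Competition death rate from a payoff
#'
#' Maps a payoff to the per-pair competition death rate
#' `d_ij = alpha + exp(-A_ij)`. Larger payoffs mean lower death rates; the
#' baseline rate `alpha` bounds the rate (and hence the population size)
#' from below no matter how large payoffs grow. For very large payoffs the
#' exponential term is clamped to zero beyond `exp_clamp` to avoid
#' underflow artifacts; payoffs themselves are never clamped.
#'
#' @param A_ij numeric vector of payoffs (finite).
#' @param alpha positive baseline competition death rate.
#' @param exp_clamp payoff above which `exp(-A)` is treated as 0 (natural
#'   log units; default 700, the double-precision underflow edge).
#' @return numeric vector of rates, each strictly greater than `alpha`
#'   (equal to `alpha` only in the clamped limit).
#' @examples
#' competition_death_rate(0, alpha = 5e-6)        # 1.000005
#' competition_death_rate(log(1000), alpha = 5e-6) # about 0.001005
#' @export
competition_death_rate <- function(A_ij, alpha, exp_clamp = 700) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) || alpha <= 0)
    stop("alpha must be a positive finite scalar")
  if (!all(is.finite(A_ij))) stop("payoff must be finite")
  e <- ifelse(A_ij > exp_clamp, 0, exp(-A_ij))
  alpha + e
}

PAIR_CLASSES <- c("dom_first", "dom_second", "bistable", "coexist")

#' Classify the two-type interaction from four payoffs
#'
#' The asymptotic outcome of the two-type competitive Lotka-Volterra
#' dynamics is fully determined by the signs of `A_ii - A_ji` and
#' `A_ij - A_jj`:
#' \describe{
#'   \item{`dom_first`}{`A_ii > A_ji` and `A_ij > A_jj`: type i excludes j.}
#'   \item{`dom_second`}{`A_ii < A_ji` and `A_ij < A_jj`: type j excludes i.}
#'   \item{`bistable`}{`A_ii > A_ji` and `A_ij < A_jj`: the winner depends
#'     on initial abundances.}
#'   \item{`coexist`}{`A_ii < A_ji` and `A_ij > A_jj`: stable interior
#'     equilibrium.}
#' }
#' Exact ties have probability zero under continuous payoffs and raise an
#' error rather than being silently broken.
#'
#' @param Aii,Aij,Aji,Ajj payoffs: `Aii` self-payoff of type i, `Aij` payoff
#'   of i against j, `Aji` payoff of j against i, `Ajj` self-payoff of j.
#' @return one of `"dom_first"`, `"dom_second"`, `"bistable"`, `"coexist"`.
#' @seealso [two_type_outcome_by_ode()] for the ODE-integration oracle.
#' @examples
#' classify_pair(1, 2, 0, 0)  # dom_first
#' classify_pair(1, 0, 0, 1)  # bistable
#' classify_pair(0, 1, 1, 0)  # coexist
#' @export
classify_pair <- function(Aii, Aij, Aji, Ajj) {
  v <- c(Aii, Aij, Aji, Ajj)
  if (length(v) != 4L || !all(is.finite(v))) stop("four finite payoffs required")
  if (Aii == Aji || Aij == Ajj)
    stop("tie in payoff comparison: pair class undefined")
  first_wins_own <- Aii > Aji   # column i: who is on top
  first_wins_other <- Aij > Ajj # column j
  if (first_wins_own && first_wins_other) "dom_first"
  else if (!first_wins_own && !first_wins_other) "dom_second"
  else if (first_wins_own) "bistable"
  else "coexist"
}

#' Classify a three-type payoff submatrix
#'
#' Classifies each of the three pairs with [classify_pair()] and reduces
#' the triplet to one of three motifs: `cyclic` (three dominance links
#' forming a directed 3-cycle, rock-paper-scissors), `noncyclic` (three
#' dominance links forming a transitive tournament, with a source type that
#' beats both others and a sink beaten by both), or `mixed` (at least one
#' link is bistable or coexistence).
#'
#' @param sub 3x3 numeric payoff matrix (rows/cols in the same type order).
#' @return A list of class `triplet_class` with elements `class`
#'   (`"cyclic"`, `"noncyclic"` or `"mixed"`), `links` (the three pair
#'   classes for pairs (1,2), (1,3), (2,3)), and for `cyclic` an
#'   `orientation` (`1` for 1->2->3->1 in "beats" direction, `-1` for the
#'   reverse), for `noncyclic` the `source` and `sink` indices.
#' @examples
#' classify_triplet(matrix(c(3, 5, 0, 1, 4, 6, 4, 2, 5), 3, 3, byrow = TRUE))
#' @export
classify_triplet <- function(sub) {
  sub <- as.matrix(sub)
  if (!all(dim(sub) == c(3L, 3L))) stop("3x3 payoff submatrix required")
  pairs <- list(c(1L, 2L), c(1L, 3L), c(2L, 3L))
  links <- vapply(pairs, function(p) {
    classify_pair(sub[p[1], p[1]], sub[p[1], p[2]], sub[p[2], p[1]], sub[p[2], p[2]])
  }, character(1))
  names(links) <- c("12", "13", "23")
  dom <- links %in% c("dom_first", "dom_second")
  if (!all(dom))
    return(structure(list(class = "mixed", links = links), class = "triplet_class"))
  # beats matrix: beats[a, b] TRUE if a dominates b
  beats <- matrix(FALSE, 3, 3)
  for (ix in seq_along(pairs)) {
    p <- pairs[[ix]]
    if (links[ix] == "dom_first") beats[p[1], p[2]] <- TRUE else beats[p[2], p[1]] <- TRUE
  }
  wins <- rowSums(beats)
  if (all(wins == 1L)) {
    orientation <- if (beats[1, 2]) 1L else -1L  # 1 beats 2 beats 3 beats 1
    structure(list(class = "cyclic", links = links, orientation = orientation),
              class = "triplet_class")
  } else {
    structure(list(class = "noncyclic", links = links,
                   source = which(wins == 2L), sink = which(wins == 0L)),
              class = "triplet_class")
  }
}

#' @export
print.triplet_class <- function(x, ...) {
  cat("triplet:", x$class)
  if (x$class == "cyclic") cat(sprintf(" (orientation %+d)", x$orientation))
  if (x$class == "noncyclic") cat(sprintf(" (source %d, sink %d)", x$source, x$sink))
  cat("\n  links:", paste(names(x$links), x$links, sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Add a mutant type to a payoff matrix
#'
#' Implements the mutation kernel: the offspring i' of parent i gets a
#' fresh type ID and, for every extant type j (including the parent and
#' itself), payoffs inherited from the parent with independent Gaussian
#' noise: `A[i', j] = A[i, j] + xi`, `A[j, i'] = A[j, i] + xi`,
#' `A[i', i'] = A[i, i] + xi`, each `xi ~ Normal(0, sigma^2)` drawn
#' independently. Pre-existing entries are untouched.
#'
#' @param m a [payoff_matrix()].
#' @param parent_id ID of an extant type.
#' @param sigma positive standard deviation of the mutation noise.
#' @return the enlarged `payoff_matrix`; the new type's ID is `m$next_id`.
#' @export
mutate_payoffs <- function(m, parent_id, sigma) {
  stopifnot(inherits(m, "payoff_matrix"))
  if (!is.numeric(sigma) || sigma < 0) stop("sigma must be non-negative")
  p <- match(as.integer(parent_id), m$type_ids)
  if (is.na(p)) stop("unknown parent_id: ", parent_id)
  n <- nrow(m$A)
  A <- matrix(0, n + 1L, n + 1L)
  A[seq_len(n), seq_len(n)] <- m$A
  A[n + 1L, seq_len(n)] <- m$A[p, ] + rnorm(n, 0, sigma)
  A[seq_len(n), n + 1L] <- m$A[, p] + rnorm(n, 0, sigma)
  A[n + 1L, n + 1L] <- m$A[p, p] + rnorm(1, 0, sigma)
  payoff_matrix(A, c(m$type_ids, m$next_id), next_id = m$next_id + 1L)
}

#' Remove extinct types from a payoff matrix
#'
#' Restricts the matrix to the surviving types; surviving entries are
#' bit-identical. Removing every type yields an empty matrix flagged by
#' `nrow(m$A) == 0` (population extinct). Removed IDs are never reissued.
#'
#' @param m a [payoff_matrix()].
#' @param dead_ids integer IDs to drop (must all be extant).
#' @return the reduced `payoff_matrix`.
#' @export
remove_types <- function(m, dead_ids) {
  stopifnot(inherits(m, "payoff_matrix"))
  dead_ids <- as.integer(dead_ids)
  idx <- match(dead_ids, m$type_ids)
  if (anyNA(idx)) stop("dead_ids contains non-extant IDs")
  if (length(idx) == 0L) return(m)
  keep <- setdiff(seq_along(m$type_ids), idx)
  payoff_matrix(m$A[keep, keep, drop = FALSE], m$type_ids[keep], next_id = m$next_id)
}

#' Read / write payoff matrices as CSV
#'
#' The CSV carries a header row of type IDs; entries are the payoffs in the
#' same row order as the header.
#'
#' @param m a [payoff_matrix()].
#' @param file path to a CSV file.
#' @return `read_payoff_csv` returns a `payoff_matrix`;
#'   `write_payoff_csv` returns `file` invisibly.
#' @export
write_payoff_csv <- function(m, file) {
  stopifnot(inherits(m, "payoff_matrix"))
  df <- as.data.frame(m$A)
  names(df) <- m$type_ids
  write.csv(df, file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_payoff_csv
#' @export
read_payoff_csv <- function(file) {
  df <- read.csv(file, check.names = FALSE)
  ids <- as.integer(names(df))
  if (anyNA(ids)) stop("CSV header must contain integer type IDs")
  payoff_matrix(as.matrix(df), ids)
}
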