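# Genealogy-conditioned payoff analysis. A rooted 3-leaf genealogy is
# reduced to five branch-wise mutation counts:
#
#            o ---- w1 ----- m -- w2 -- i        (i's lineage)
#             \
#              x ---- n -- y -- j                (j's lineage)
#                      \-- z -- k                (k's lineage)
#
# o is the last common ancestor of the triplet, n the last common ancestor
# of the close pair (j, k), and td the moment j's and k's lineages diverge.
# w1 counts mutations on i's lineage before td, w2 after td; x is the
# shared (j,k) stem, y and z the terminal branches. Every divergence event
# is itself a mutation on the diverging (offspring) branch, so w1 + x >= 1
# and y + z >= 1 in any genealogy that can actually occur.
#
# Replaying the genealogy under the mutation kernel (fresh payoff row and
# column with independent Gaussian noise at every mutation) makes the nine
# payoff entries of the resulting 3x3 matrix jointly Gaussian; triplet
# classification probabilities depend only on the branch counts, not on
# sigma or on the event interleaving within the pre-td and post-td
# segments.

#' Rooted three-leaf genealogy with branch mutation counts
#'
#' @param w1 mutations on the outgroup (i) lineage before the close pair
#'   diverges (from the root o to td).
#' @param w2 mutations on the i lineage after td.
#' @param x mutations on the shared stem from o to n, the common ancestor
#'   of the close pair.
#' @param y,z mutations on the terminal branches from n to the two close
#'   leaves.
#' @param close_pair which leaf pair shares the more recent common
#'   ancestor; a label only (chi is invariant under leaf relabeling).
#' @return object of class `genealogy_triplet`.
#' @examples
#' g <- genealogy_triplet(w1 = 3, w2 = 1, x = 2, y = 4, z = 5)
#' fl(g)  # 10/15
#' @export
genealogy_triplet <- function(w1, w2, x, y, z, close_pair = "jk") {
  cnt <- c(w1 = w1, w2 = w2, x = x, y = y, z = z)
  if (any(!is.finite(cnt)) || any(cnt < 0) || any(cnt != round(cnt)))
    stop("branch mutation counts must be non-negative integers")
  if (w1 + x < 1)
    stop("w1 + x >= 1 required: the divergence of i's lineage from the stem is itself a mutation")
  if (y + z < 1)
    stop("y + z >= 1 required: the divergence of j and k is itself a mutation")
  if ((w1 + w2) + (x + y) < 1 || (w1 + w2) + (x + z) < 1)
    stop("degenerate genealogy: two leaves coincide")
  structure(list(w1 = as.numeric(w1), w2 = as.numeric(w2), x = as.numeric(x),
                 y = as.numeric(y), z = as.numeric(z),
                 close_pair = close_pair),
            class = "genealogy_triplet")
}

#' @export
print.genealogy_triplet <- function(x, ...) {
  cat(sprintf("genealogy_triplet (close pair %s): w1=%g w2=%g x=%g y=%g z=%g  Fl=%.3f\n",
              x$close_pair, x$w1, x$w2, x$x, x$y, x$z, fl(x)))
  invisible(x)
}

#' Fraction of mutations accumulated after the last divergence
#'
#' `Fl = (w2 + y + z) / (w2 + y + z + w1 + x)`: the share of all mutations
#' since the last common ancestor that fell after the close pair diverged
#' (time td), when all three lineages evolve independently. Large `Fl`
#' decorrelates the triplet's payoffs and promotes cyclic dominance.
#'
#' @param g a [genealogy_triplet()].
#' @return value in `[0, 1]`.
#' @export
fl <- function(g) {
  stopifnot(inherits(g, "genealogy_triplet"))
  post <- g$w2 + g$y + g$z
  tot <- post + g$w1 + g$x
  if (tot == 0) return(NA_real_)
  post / tot
}

# Canonical replay schedule: a list of operations on lineages, each either
# spawn (divergence: offspring copies the parent's payoff row/column with
# fresh noise; both lineages persist), rename, or mutate (the lineage's
# current type is replaced by its mutant `times` times in a row; k
# successive mutations add k independent noises per entry, so batches are
# exact). Interleaving within the pre-td and post-td segments does not
# affect the payoff distribution; the canonical schedule batches each
# branch, and `shuffle_segments` randomizes the within-segment event order
# (used to test order invariance).
genealogy_ops <- function(g, shuffle_segments = FALSE) {
  ops <- list()
  add <- function(type, a, b = NULL, times = 1)
    ops[[length(ops) + 1L]] <<- list(type = type, a = a, b = b, times = times)
  add_mutations <- function(counts) {
    # counts: named vector of per-lineage mutation counts within a segment
    counts <- counts[counts > 0]
    if (!length(counts)) return(invisible())
    if (shuffle_segments) {
      ev <- sample(rep(names(counts), counts))
      rl <- rle(ev)
      for (q in seq_along(rl$values)) add("mutate", rl$values[q], times = rl$lengths[q])
    } else {
      for (u in names(counts)) add("mutate", u, times = counts[[u]])
    }
  }
  if (g$w1 >= 1) {               # i's side carries the root divergence
    add("spawn", "s", "i")       # root lineage continues as the stem
    add_mutations(c(i = g$w1 - 1, s = g$x))
  } else {                       # x >= 1: the stem diverges, root continues as i
    add("rename", "s", "i")
    add("spawn", "i", "s")
    add_mutations(c(s = g$x - 1))
  }
  if (g$y >= 1) {                # j diverges; the stem continues as k
    add("spawn", "s", "j")
    add("rename", "s", "k")
    add_mutations(c(i = g$w2, j = g$y - 1, k = g$z))
  } else {                       # z >= 1: k diverges; the stem continues as j
    add("spawn", "s", "k")
    add("rename", "s", "j")
    add_mutations(c(i = g$w2, k = g$z - 1, j = g$y))
  }
  ops
}

#' Sample one payoff matrix conditioned on a genealogy
#'
#' Replays the genealogy's divergence and mutation events in chronological
#' order, applying the mutation kernel (a fresh payoff row and column with
#' independent `Normal(0, sigma^2)` noise per entry) to the lineages extant
#' at each moment. The ancestral self-payoff is fixed at 0: triplet
#' classification depends only on payoff comparisons that share the
#' ancestral level, so the level cancels.
#'
#' @param g a [genealogy_triplet()].
#' @param sigma mutation noise standard deviation.
#' @param shuffle_segments randomize the event order within the pre- and
#'   post-divergence segments (the payoff distribution is invariant).
#' @return 3x3 payoff matrix, rows/columns ordered (i, j, k).
#' @export
sample_matrix_given_genealogy <- function(g, sigma = 1, shuffle_segments = FALSE) {
  stopifnot(inherits(g, "genealogy_triplet"))
  A <- matrix(0, 1, 1, dimnames = list("s", "s"))
  for (op in genealogy_ops(g, shuffle_segments)) {
    if (op$type == "rename") {
      rn <- rownames(A); rn[rn == op$a] <- op$b
      rownames(A) <- colnames(A) <- rn
    } else if (op$type == "spawn") {
      p <- op$a; ch <- op$b
      nl <- nrow(A)
      lbl <- c(rownames(A), ch)
      B <- matrix(0, nl + 1L, nl + 1L, dimnames = list(lbl, lbl))
      B[seq_len(nl), seq_len(nl)] <- A
      for (w in rownames(A)) {
        B[ch, w] <- A[p, w] + rnorm(1, 0, sigma)
        B[w, ch] <- A[w, p] + rnorm(1, 0, sigma)
      }
      B[ch, ch] <- A[p, p] + rnorm(1, 0, sigma)
      A <- B
    } else { # mutate: replace the lineage's type by its own mutant, op$times times
      u <- op$a
      others <- setdiff(rownames(A), u)
      for (k in seq_len(op$times)) {
        A[u, others] <- A[u, others] + rnorm(length(others), 0, sigma)
        A[others, u] <- A[others, u] + rnorm(length(others), 0, sigma)
        A[u, u] <- A[u, u] + rnorm(1, 0, sigma)
      }
    }
  }
  A[c("i", "j", "k"), c("i", "j", "k")]
}

#' Covariance of the nine payoff entries implied by a genealogy
#'
#' Accumulates, event by event along the replay schedule, the exact joint
#' covariance of the 3x3 matrix entries under the mutation kernel: a
#' divergence copies the parent's covariance rows and adds `sigma^2` to the
#' new entries' variances; a mutation adds `sigma^2` to the variance of
#' every entry in the mutated lineage's row and column, leaving covariances
#' untouched (each entry receives its own independent noise).
#'
#' @inheritParams sample_matrix_given_genealogy
#' @return 9x9 covariance matrix; entry order is the column-major order of
#'   the (i, j, k) payoff matrix (`A_ii, A_ji, A_ki, A_ij, ...`), with
#'   dimnames like `"i,j"` (row type, column type).
#' @export
genealogy_entry_covariance <- function(g, sigma = 1) {
  stopifnot(inherits(g, "genealogy_triplet"))
  s2 <- sigma^2
  lineages <- "s"
  ekey <- function(r, c) paste(r, c, sep = ",")
  keys <- ekey("s", "s")
  S <- matrix(0, 1, 1, dimnames = list(keys, keys))
  for (op in genealogy_ops(g)) {
    if (op$type == "rename") {
      lineages[lineages == op$a] <- op$b
      nk <- rownames(S)
      for (pos in 1:2) {
        parts <- do.call(rbind, strsplit(nk, ","))
        parts[parts[, pos] == op$a, pos] <- op$b
        nk <- paste(parts[, 1], parts[, 2], sep = ",")
      }
      dimnames(S) <- list(nk, nk)
    } else if (op$type == "spawn") {
      p <- op$a; ch <- op$b
      new_lin <- c(lineages, ch)
      # each new entry involving ch copies the corresponding parent entry
      src <- character(0); dst <- character(0)
      for (w in lineages) {
        dst <- c(dst, ekey(ch, w), ekey(w, ch))
        src <- c(src, ekey(p, w), ekey(w, p))
      }
      dst <- c(dst, ekey(ch, ch)); src <- c(src, ekey(p, p))
      old <- rownames(S)
      allk <- c(old, dst)
      M <- matrix(0, length(allk), length(old), dimnames = list(allk, old))
      M[cbind(old, old)] <- 1
      M[cbind(dst, src)] <- 1
      S <- M %*% S %*% t(M)
      dimnames(S) <- list(allk, allk)
      diag(S)[match(dst, allk)] <- diag(S)[match(dst, allk)] + s2
      lineages <- new_lin
    } else {
      u <- op$a
      touched <- unique(c(vapply(lineages, function(w) ekey(u, w), character(1)),
                          vapply(lineages, function(w) ekey(w, u), character(1))))
      ix <- match(touched, rownames(S))
      diag(S)[ix] <- diag(S)[ix] + op$times * s2
    }
  }
  ord <- as.vector(outer(c("i", "j", "k"), c("i", "j", "k"),
                         function(r, c) paste(r, c, sep = ",")))
  S[ord, ord]
}

# draw n samples of the 9 entries from the genealogy's Gaussian law
sample_entries_given_genealogy <- function(g, n, sigma = 1) {
  S <- genealogy_entry_covariance(g, sigma)
  e <- eigen(S, symmetric = TRUE)
  L <- e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow = 9)
  Z <- matrix(rnorm(n * 9), n, 9)
  E <- Z %*% t(L)
  colnames(E) <- rownames(S)
  E
}

#' Monte-Carlo estimate of chi conditioned on a genealogy
#'
#' Samples payoff matrices from the exact Gaussian law the genealogy
#' induces under the mutation kernel (the same distribution
#' [sample_matrix_given_genealogy()] draws from, sampled through its
#' covariance so the cost does not grow with the mutation counts),
#' classifies each triplet, and estimates
#' `chi = P(cyclic) / P(cyclic or noncyclic)` with a binomial standard
#' error. Mixed samples are excluded from the denominator. chi is
#' invariant to `sigma`, which only scales all entries jointly.
#'
#' @inheritParams sample_matrix_given_genealogy
#' @param n_samples number of Monte-Carlo draws (>= 1).
#' @return list: `chi`, `se`, `n_cyclic`, `n_dominance`, `n_samples`;
#'   `chi` is `NA` if no dominance triplet was sampled.
#' @examples
#' g <- genealogy_triplet(w1 = 0, w2 = 1000, x = 1, y = 1, z = 1)
#' chi_given_genealogy(g, n_samples = 1e4)
#' @export
chi_given_genealogy <- function(g, sigma = 1, n_samples = 1e5) {
  stopifnot(inherits(g, "genealogy_triplet"), n_samples >= 1)
  E <- sample_entries_given_genealogy(g, n_samples, sigma)
  res <- chi_from_codes(classify_triplets_bulk(E))
  res$n_samples <- n_samples
  res
}

#' Search for genealogies that minimize or maximize chi
#'
#' Deterministic (given the RNG seed) screen-and-refine search over branch
#' mutation counts on a logarithmic grid, including configurations with
#' nearly all mutations on a single branch (the asymptotic regimes).
#' Candidates are ranked by the fraction `Fl` of post-divergence mutations
#' — large `Fl` first when maximizing, small first when minimizing — the
#' first `budget` candidates are screened with `n_screen` samples each, and
#' the best few are re-estimated with `n_final` samples.
#'
#' @param direction `"max"` or `"min"`.
#' @param budget maximum number of candidate genealogies screened.
#' @param sigma mutation noise sd (chi is sigma-invariant; kept for
#'   interface symmetry).
#' @param n_screen,n_final Monte-Carlo sample sizes for the screening and
#'   refinement stages.
#' @param grid branch-count levels used to build the candidate grid.
#' @param refine_top number of screened candidates re-estimated at
#'   `n_final`.
#' @return list: `genealogy` (the best [genealogy_triplet()]), `chi`, `se`,
#'   `n_dominance`, `screened` (data.frame of all screened candidates).
#' @export
search_extreme_chi <- function(direction = c("max", "min"), budget = 400,
                               sigma = 1, n_screen = 2e4, n_final = 3e5,
                               grid = c(0, 1, 10, 100, 1e4, 1e6),
                               refine_top = 5L) {
  direction <- match.arg(direction)
  gr <- expand.grid(w1 = grid, w2 = grid, x = grid,
                    y = grid[grid >= 1], z = grid[grid >= 1])
  gr <- gr[gr$y <= gr$z, ]                       # j/k label symmetry
  gr <- gr[gr$w1 + gr$x >= 1, ]                  # realizable genealogies
  tot_post <- gr$w2 + gr$y + gr$z
  gr$fl <- tot_post / (tot_post + gr$w1 + gr$x)
  ord <- if (direction == "max")
    order(-gr$fl, -(tot_post + gr$w1 + gr$x)) else
    order(gr$fl, -(gr$w1 + gr$x))
  gr <- gr[ord, , drop = FALSE]
  gr <- gr[seq_len(min(budget, nrow(gr))), , drop = FALSE]
  gr$chi <- NA_real_
  for (r in seq_len(nrow(gr))) {
    g <- genealogy_triplet(gr$w1[r], gr$w2[r], gr$x[r], gr$y[r], gr$z[r])
    gr$chi[r] <- chi_given_genealogy(g, sigma, n_screen)$chi
  }
  score <- if (direction == "max") -gr$chi else gr$chi
  top <- order(score)[seq_len(min(refine_top, nrow(gr)))]
  best <- NULL; best_chi <- NULL
  for (r in top) {
    g <- genealogy_triplet(gr$w1[r], gr$w2[r], gr$x[r], gr$y[r], gr$z[r])
    res <- chi_given_genealogy(g, sigma, n_final)
    if (is.null(best) ||
        (direction == "max" && res$chi > best_chi) ||
        (direction == "min" && res$chi < best_chi)) {
      best <- g; best_chi <- res$chi
    }
  }
  # report from a fresh, independent estimate of the selected genealogy so
  # the result carries no winner's-curse selection bias
  best_res <- chi_given_genealogy(best, sigma, n_final)
  list(genealogy = best, chi = best_res$chi, se = best_res$se,
       n_dominance = best_res$n_dominance, screened = gr)
}

#' Extract the genealogy of a triplet from a simulation log
#'
#' Walks the parent links recorded at every mutation event back to the last
#' common ancestor of three extant (or extinct) types and reduces the
#' genealogy to the five branch mutation counts. Each edge of the type tree
#' is one mutation; mutations of extinct intermediaries along a path are
#' counted like any other. The close pair is the pair with the most recent
#' common ancestor; ties (all pairwise ancestors equal the root of the
#' triplet) are resolved by the order of lineage divergences: the outgroup
#' is the lineage that split first.
#'
#' @param log data.frame with columns `t_mut`, `parent`, `child` (e.g.
#'   `sim$genealogy`), one row per mutation event; the founder type is the
#'   one that never appears as a child.
#' @param triplet three distinct type IDs present in the log (as child or
#'   founder).
#' @return a [genealogy_triplet()]; attributes `leaves` (named i, j, k) and
#'   `lca` give the mapping back to type IDs.
#' @export
extract_genealogy <- function(log, triplet) {
  triplet <- as.integer(triplet)
  if (length(triplet) != 3L || anyDuplicated(triplet)) stop("three distinct IDs required")
  parent <- setNames(as.integer(log$parent), as.character(log$child))
  born <- setNames(as.integer(log$t_mut), as.character(log$child))
  known <- unique(c(log$parent, log$child))
  if (!all(triplet %in% known)) stop("triplet members missing from the genealogy log")
  path_up <- function(id) {        # leaf -> ... -> founder
    out <- id
    while (as.character(id) %in% names(parent)) {
      id <- parent[[as.character(id)]]
      out <- c(out, id)
    }
    out
  }
  paths <- lapply(triplet, path_up)
  depth <- function(id) if (as.character(id) %in% names(born)) born[[as.character(id)]] else -1L
  lca2 <- function(p1, p2) {
    common <- intersect(p1, p2)
    common[which.max(vapply(common, depth, numeric(1)))]
  }
  l12 <- lca2(paths[[1]], paths[[2]])
  l13 <- lca2(paths[[1]], paths[[3]])
  l23 <- lca2(paths[[2]], paths[[3]])
  pl <- c(depth(l12), depth(l13), depth(l23))
  o_candidates <- c(l12, l13, l23)
  o <- o_candidates[which.min(pl)]
  # first-edge creation event of each path below a node
  first_edge_after <- function(p, node) {
    pos <- match(node, p)
    if (pos == 1L) Inf else born[[as.character(p[pos - 1L])]]
  }
  if (max(pl) > min(pl)) {
    close_idx <- list(c(1L, 2L), c(1L, 3L), c(2L, 3L))[[which.max(pl)]]
  } else {
    # all three pairwise ancestors coincide: outgroup = first lineage to split
    fe <- vapply(1:3, function(q) first_edge_after(paths[[q]], o), numeric(1))
    close_idx <- setdiff(1:3, which.min(fe))
  }
  i_idx <- setdiff(1:3, close_idx)
  n_node <- lca2(paths[[close_idx[1]]], paths[[close_idx[2]]])
  td <- min(first_edge_after(paths[[close_idx[1]]], n_node),
            first_edge_after(paths[[close_idx[2]]], n_node))
  if (!is.finite(td)) stop("degenerate triplet: two members on one unbroken lineage")
  edges_events <- function(p, from, to) { # creation events of edges on from->to segment
    a <- match(from, p); b <- match(to, p)
    if (a == b) return(numeric(0))
    vapply(p[seq(b - 1L, a)], function(id) born[[as.character(id)]], numeric(1))
  }
  pi <- paths[[i_idx]]
  ev_i <- edges_events(pi, triplet[i_idx], o)
  w1 <- sum(ev_i < td); w2 <- sum(ev_i > td)
  x <- length(edges_events(paths[[close_idx[1]]], n_node, o))
  y <- length(edges_events(paths[[close_idx[1]]], triplet[close_idx[1]], n_node))
  z <- length(edges_events(paths[[close_idx[2]]], triplet[close_idx[2]], n_node))
  g <- genealogy_triplet(w1, w2, x, y, z)
  attr(g, "leaves") <- c(i = triplet[i_idx], j = triplet[close_idx[1]],
                         k = triplet[close_idx[2]])
  attr(g, "lca") <- c(o = o, n = n_node)
  g
}

#' Write / read a genealogy as Newick plus JSON sidecar
#'
#' The Newick tree has the three leaves with integer branch lengths equal
#' to the mutation counts (`i` carries `w1 + w2`; the pre/post split at td
#' lives in the JSON sidecar written alongside as `<path>.json`).
#'
#' @param g a [genealogy_triplet()].
#' @param path file path for the Newick tree; the sidecar is
#'   `paste0(path, ".json")`.
#' @param labels leaf labels, default `c("i", "j", "k")` (use type IDs when
#'   exporting simulation triplets).
#' @return `write_genealogy` returns `path` invisibly; `read_genealogy`
#'   returns the [genealogy_triplet()].
#' @export
write_genealogy <- function(g, path, labels = c("i", "j", "k")) {
  stopifnot(inherits(g, "genealogy_triplet"))
  nwk <- sprintf("(%s:%d,(%s:%d,%s:%d)n:%d)o;",
                 labels[1], as.integer(g$w1 + g$w2),
                 labels[2], as.integer(g$y), labels[3], as.integer(g$z),
                 as.integer(g$x))
  writeLines(nwk, path)
  jsonlite::write_json(
    list(close_pair = g$close_pair, w1 = g$w1, w2 = g$w2, x = g$x,
         y = g$y, z = g$z, Fl = fl(g)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_genealogy
#' @export
read_genealogy <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  g <- genealogy_triplet(side$w1, side$w2, side$x, side$y, side$z,
                         close_pair = side$close_pair)
  tree <- ape::read.tree(path)
  if (!is.null(tree)) {
    len <- tree$edge.length[match(seq_along(tree$tip.label), tree$edge[, 2])]
    expect <- c(g$w1 + g$w2, g$y, g$z)
    if (length(len) == 3 && !isTRUE(all.equal(sort(as.numeric(len)), sort(expect))))
      warning("Newick branch lengths disagree with the JSON sidecar; using the sidecar")
  }
  g
}
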