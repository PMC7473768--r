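# Interaction-network and triplet statistics: from a payoff matrix to the
# complete pairwise network, its triplet motif counts, the fraction chi of
# cyclic dominance among dominance triplets, and triplet lifespans across
# mutation-event snapshots.

#' Build the pairwise interaction network of a payoff matrix
#'
#' One link per unordered pair of extant types, classified with
#' [classify_pair()]. Dominance links carry the winner's ID.
#'
#' @param m a [payoff_matrix()] with at least two types.
#' @return object of class `interaction_network`: list with `ids` and
#'   `links` (data.frame `a`, `b`, `class` in
#'   dominance/bistability/coexistence, `winner` ID or NA).
#' @export
build_network <- function(m) {
  stopifnot(inherits(m, "payoff_matrix"))
  n <- length(m$type_ids)
  if (n < 2L) stop("need at least two types to build a network")
  pr <- combn(n, 2)
  a <- pr[1, ]; b <- pr[2, ]
  A <- m$A
  cls <- character(ncol(pr)); winner <- rep(NA_integer_, ncol(pr))
  for (k in seq_len(ncol(pr))) {
    i <- a[k]; j <- b[k]
    pc <- tryCatch(classify_pair(A[i, i], A[i, j], A[j, i], A[j, j]),
                   error = function(e) stop("tie at pair (", m$type_ids[i], ", ",
                                            m$type_ids[j], "): ", conditionMessage(e)))
    if (pc == "dom_first") { cls[k] <- "dominance"; winner[k] <- m$type_ids[i] }
    else if (pc == "dom_second") { cls[k] <- "dominance"; winner[k] <- m$type_ids[j] }
    else if (pc == "bistable") cls[k] <- "bistability"
    else cls[k] <- "coexistence"
  }
  structure(list(ids = m$type_ids,
                 links = data.frame(a = m$type_ids[a], b = m$type_ids[b],
                                    class = cls, winner = winner)),
            class = "interaction_network")
}

#' @export
print.interaction_network <- function(x, ...) {
  cat(sprintf("interaction_network: %d types, %d links\n",
              length(x$ids), nrow(x$links)))
  print(table(x$links$class))
  invisible(x)
}

#' Proportions of link types in a network
#'
#' Dominance pools both orientations. For i.i.d. continuous random payoffs
#' the expected proportions are 0.50 dominance, 0.25 bistability and
#' 0.25 coexistence.
#'
#' @param net an [build_network()] result.
#' @return named numeric vector over dominance/bistability/coexistence,
#'   summing to one.
#' @export
link_type_proportions <- function(net) {
  stopifnot(inherits(net, "interaction_network"))
  if (nrow(net$links) == 0L) stop("network has no links")
  tab <- table(factor(net$links$class,
                      levels = c("dominance", "bistability", "coexistence")))
  setNames(as.vector(tab) / sum(tab), names(tab))
}

# Vectorized triplet classification of one payoff matrix.
# Returns data.frame: a,b,c (type IDs, ascending matrix order), code
# (0 mixed / 1 cyclic / 2 noncyclic), orient (+-1 for cyclic: +1 means
# a beats b beats c beats a), source, sink (IDs, noncyclic only).
triplet_table <- function(A, ids) {
  n <- nrow(A)
  if (n < 3L) stop("need n >= 3")
  tri <- combn(n, 3)
  i <- tri[1, ]; j <- tri[2, ]; k <- tri[3, ]
  ix <- function(r, c) A[cbind(r, c)]
  s12a <- ix(i, i) > ix(j, i); s12b <- ix(i, j) > ix(j, j); dom12 <- s12a == s12b
  s13a <- ix(i, i) > ix(k, i); s13b <- ix(i, k) > ix(k, k); dom13 <- s13a == s13b
  s23a <- ix(j, j) > ix(k, j); s23b <- ix(j, k) > ix(k, k); dom23 <- s23a == s23b
  alldom <- dom12 & dom13 & dom23
  o1 <- s12a + s13a
  o2 <- (!s12a) + s23a
  o3 <- (!s13a) + (!s23a)
  cyc <- alldom & o1 == 1L & o2 == 1L & o3 == 1L
  code <- integer(length(i)); code[alldom] <- 2L; code[cyc] <- 1L
  orient <- ifelse(cyc, ifelse(s12a, 1L, -1L), NA_integer_)
  src <- rep(NA_integer_, length(i)); snk <- src
  nc <- which(alldom & !cyc)
  if (length(nc)) {
    om <- cbind(o1[nc], o2[nc], o3[nc])
    src_pos <- max.col(om)  # out-degree 2
    snk_pos <- max.col(-om) # out-degree 0
    trip_ids <- cbind(ids[i[nc]], ids[j[nc]], ids[k[nc]])
    src[nc] <- trip_ids[cbind(seq_along(nc), src_pos)]
    snk[nc] <- trip_ids[cbind(seq_along(nc), snk_pos)]
  }
  data.frame(a = ids[i], b = ids[j], c = ids[k], code = code,
             orient = orient, source = src, sink = snk)
}

#' Count triplet motifs of a payoff matrix or network
#'
#' Enumerates all `choose(n, 3)` type triplets and classifies each as
#' cyclic dominance, non-cyclic dominance, or mixed (at least one link not
#' a dominance link). For fewer than three types the counts are undefined:
#' the result carries `valid = FALSE` and NA counts so callers can exclude
#' it from ensemble averages, rather than a silent zero.
#'
#' @param m a [payoff_matrix()] (or plain square matrix).
#' @return list with `counts` (named: cyclic, noncyclic, mixed),
#'   `proportions` (counts / C(n,3)), `n_triplets`, `valid`.
#' @export
count_triplets <- function(m) {
  A <- if (inherits(m, "payoff_matrix")) m$A else as.matrix(m)
  ids <- if (inherits(m, "payoff_matrix")) m$type_ids else seq_len(nrow(A)) - 1L
  n <- nrow(A)
  if (n < 3L)
    return(list(counts = c(cyclic = NA_integer_, noncyclic = NA_integer_,
                           mixed = NA_integer_),
                proportions = c(cyclic = NA_real_, noncyclic = NA_real_,
                                mixed = NA_real_),
                n_triplets = choose(n, 3), valid = FALSE))
  tt <- triplet_table(A, ids)
  counts <- c(cyclic = sum(tt$code == 1L), noncyclic = sum(tt$code == 2L),
              mixed = sum(tt$code == 0L))
  list(counts = counts, proportions = counts / nrow(tt),
       n_triplets = nrow(tt), valid = TRUE)
}

#' Fraction of cyclic dominance among dominance triplets
#'
#' `chi = cyclic / (cyclic + noncyclic)`. Mixed triplets are not part of
#' the denominator. With zero dominance triplets the fraction is undefined
#' and `NA` is returned, so ensemble averages can exclude the sample.
#'
#' @param counts named vector (or list) with elements `cyclic` and
#'   `noncyclic`, e.g. `count_triplets(m)$counts`.
#' @return chi in `[0, 1]`, or `NA` when there are no dominance triplets.
#' @examples
#' chi(c(cyclic = 2, noncyclic = 24))  # 1/13
#' @export
chi <- function(counts) {
  cyc <- as.numeric(counts[["cyclic"]])
  non <- as.numeric(counts[["noncyclic"]])
  if (is.na(cyc) || is.na(non) || cyc + non == 0) return(NA_real_)
  cyc / (cyc + non)
}

#' Per-snapshot triplet statistics of a simulation
#'
#' For every mutation-event snapshot of a [simulate_population()] run,
#' computes N, n, link-type counts and triplet motif counts plus chi.
#' Snapshots with `n < 3` carry NA triplet columns (they are excluded from
#' ensemble averages, matching the convention that triplet quantities are
#' only defined for n >= 3).
#'
#' @param sim a `cyclodom_sim`.
#' @return data.frame with one row per snapshot: `t_mut`, `N`, `n`,
#'   `cyclic`, `noncyclic`, `mixed`, `prop_cyclic`, `prop_noncyclic`,
#'   `chi`.
#' @export
triplet_series <- function(sim) {
  stopifnot(inherits(sim, "cyclodom_sim"))
  s <- sim$snapshots
  nsnap <- length(s$t_mut)
  out <- data.frame(t_mut = s$t_mut, N = s$N, n = s$n,
                    cyclic = NA_integer_, noncyclic = NA_integer_,
                    mixed = NA_integer_, prop_cyclic = NA_real_,
                    prop_noncyclic = NA_real_, chi = NA_real_)
  for (r in seq_len(nsnap)) {
    if (s$n[r] < 3L) next
    tt <- triplet_table(s$A[[r]], s$ids[[r]])
    cyc <- sum(tt$code == 1L); non <- sum(tt$code == 2L)
    tot <- nrow(tt)
    out$cyclic[r] <- cyc; out$noncyclic[r] <- non; out$mixed[r] <- tot - cyc - non
    out$prop_cyclic[r] <- cyc / tot; out$prop_noncyclic[r] <- non / tot
    out$chi[r] <- if (cyc + non > 0) cyc / (cyc + non) else NA_real_
  }
  out
}

# identity key of a dominance triplet: sorted IDs + class + orientation
# (cyclic) or source/sink (noncyclic). A change of class or orientation is
# a different motif and closes the record.
triplet_keys <- function(A, ids) {
  if (nrow(A) < 3L) return(character())
  tt <- triplet_table(A, ids)
  tt <- tt[tt$code != 0L, , drop = FALSE]
  if (!nrow(tt)) return(character())
  ifelse(tt$code == 1L,
         paste0(tt$a, "_", tt$b, "_", tt$c, "|C|", tt$orient),
         paste0(tt$a, "_", tt$b, "_", tt$c, "|N|", tt$source, ">", tt$sink))
}

#' Track dominance-triplet lifespans across snapshots
#'
#' A record opens at the first snapshot where a given unordered set of
#' three type IDs forms a cyclic (resp. non-cyclic) dominance triplet with
#' a given orientation (resp. source/sink), and closes at the first later
#' snapshot where it does not — because a member went extinct
#' (cause `"extinction"`) or a link changed class or direction
#' (cause `"link_flip"`). A class flip closes one record and opens a new
#' one: the flipped motif is a different triplet. Lifespans are measured in
#' mutation events. Records still open at the last snapshot are
#' right-censored (`censored = TRUE`); their partial lifespan is reported
#' but they are excluded from [lifespan_ccdf()].
#'
#' @param sim a `cyclodom_sim`, or a list with elements `t_mut` (integer
#'   vector), `ids` (list), `A` (list of matrices) ordered by `t_mut`.
#' @param window optional `c(lo, hi)` restricting tracking to snapshots
#'   with `lo <= t_mut <= hi` (e.g. a steady-state window).
#' @return data.frame: `key`, `class` ("cyclic"/"noncyclic"), `t_formed`,
#'   `t_destroyed` (NA if censored), `lifespan`, `cause`, `censored`.
#' @export
track_lifespans <- function(sim, window = NULL) {
  s <- if (inherits(sim, "cyclodom_sim")) sim$snapshots else sim
  t_mut <- s$t_mut
  if (is.unsorted(t_mut, strictly = TRUE)) stop("snapshots must be strictly ordered by t_mut")
  keep <- if (is.null(window)) seq_along(t_mut) else
    which(t_mut >= window[1] & t_mut <= window[2])
  open <- new.env(parent = emptyenv())
  rec <- list()
  last_ids <- NULL
  for (r in keep) {
    tm <- t_mut[r]
    ids_now <- s$ids[[r]]
    keys_now <- triplet_keys(s$A[[r]], ids_now)
    open_keys <- ls(open)
    gone <- setdiff(open_keys, keys_now)
    for (kk in gone) {
      t0 <- get(kk, envir = open)
      members <- as.integer(strsplit(strsplit(kk, "|", fixed = TRUE)[[1]][1], "_")[[1]])
      cause <- if (all(members %in% ids_now)) "link_flip" else "extinction"
      rec[[length(rec) + 1L]] <- data.frame(
        key = kk, class = if (grepl("|C|", kk, fixed = TRUE)) "cyclic" else "noncyclic",
        t_formed = t0, t_destroyed = tm, lifespan = tm - t0,
        cause = cause, censored = FALSE)
      rm(list = kk, envir = open)
    }
    for (kk in setdiff(keys_now, open_keys)) assign(kk, tm, envir = open)
    last_ids <- ids_now
  }
  t_end <- if (length(keep)) t_mut[keep[length(keep)]] else NA_integer_
  for (kk in ls(open)) {
    t0 <- get(kk, envir = open)
    rec[[length(rec) + 1L]] <- data.frame(
      key = kk, class = if (grepl("|C|", kk, fixed = TRUE)) "cyclic" else "noncyclic",
      t_formed = t0, t_destroyed = NA_integer_, lifespan = t_end - t0,
      cause = NA_character_, censored = TRUE)
  }
  if (!length(rec))
    return(data.frame(key = character(), class = character(),
                      t_formed = integer(), t_destroyed = integer(),
                      lifespan = integer(), cause = character(),
                      censored = logical()))
  do.call(rbind, rec)
}

#' Complementary cumulative distribution of lifespans
#'
#' `CCDF(x)` is the fraction of lifespans strictly greater than `x`;
#' `CCDF(-1) = 1` and the function is non-increasing. Censored records must
#' be excluded by the caller (see [track_lifespans()]).
#'
#' @param lifespans non-negative integer lifespans (uncensored).
#' @return data.frame with columns `x` (from -1 to `max(lifespans)`) and
#'   `ccdf`.
#' @examples
#' lifespan_ccdf(c(1, 1, 2))
#' @export
lifespan_ccdf <- function(lifespans) {
  if (!length(lifespans)) stop("at least one lifespan required")
  if (any(lifespans < 0)) stop("lifespans must be non-negative")
  xs <- seq(-1L, max(lifespans))
  data.frame(x = xs,
             ccdf = vapply(xs, function(v) mean(lifespans > v), numeric(1)))
}
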