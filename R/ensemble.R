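# Experiment orchestration: ensembles of independent realizations,
# mutation-event-aligned ensemble averages, alpha sweeps, and structured
# CSV/JSON export. Realization r of an ensemble uses seed = base_seed + r,
# so ensembles are reproducible and embarrassingly parallel in principle
# (results are merged by realization index).

#' Run an ensemble of independent realizations
#'
#' Runs `n_realizations` simulations with seeds `seed + 1, ..., seed + n`,
#' computes each run's per-mutation-event triplet statistics, and averages
#' N, n, triplet proportions and chi across realizations at each mutation
#' event. Extinct realizations are excluded from the averages (their count
#' is reported); triplet quantities additionally average only over
#' realizations with `n >= 3` at that event.
#'
#' @param params a [model_params()].
#' @param t_mut_max mutation events per realization.
#' @param n_realizations number of independent runs.
#' @param seed base seed.
#' @param ... passed to [simulate_population()].
#' @return object of class `cyclodom_ensemble`: list with `average`
#'   (data.frame: `t_mut`, `N`, `n`, `prop_cyclic`, `prop_noncyclic`,
#'   `chi`, `n_runs`, `n_runs_triplet`), `runs` (list of `cyclodom_sim`),
#'   `series` (list of per-run [triplet_series()]), `n_survived`, `params`,
#'   `seed`.
#' @export
run_ensemble <- function(params, t_mut_max, n_realizations, seed = 1, ...) {
  stopifnot(n_realizations >= 1)
  runs <- vector("list", n_realizations)
  series <- vector("list", n_realizations)
  for (r in seq_len(n_realizations)) {
    runs[[r]] <- simulate_population(params, t_mut_max, seed = seed + r, ...)
    series[[r]] <- triplet_series(runs[[r]])
  }
  survived <- !vapply(runs, function(s) s$extinct, logical(1))
  if (!any(survived))
    stop("all ", n_realizations, " realizations went extinct; ",
         "check parameters (lambda_b - lambda_d vs alpha scale)")
  avg <- data.frame(t_mut = seq_len(t_mut_max), N = NA_real_, n = NA_real_,
                    prop_cyclic = NA_real_, prop_noncyclic = NA_real_,
                    chi = NA_real_, n_runs = 0L, n_runs_triplet = 0L)
  for (t in seq_len(t_mut_max)) {
    Ns <- c(); ns <- c(); pc <- c(); pn <- c(); ch <- c()
    for (r in which(survived)) {
      ts <- series[[r]]
      row <- which(ts$t_mut == t)
      if (!length(row)) next
      Ns <- c(Ns, ts$N[row]); ns <- c(ns, ts$n[row])
      if (!is.na(ts$prop_cyclic[row])) {
        pc <- c(pc, ts$prop_cyclic[row]); pn <- c(pn, ts$prop_noncyclic[row])
        if (!is.na(ts$chi[row])) ch <- c(ch, ts$chi[row])
      }
    }
    avg$n_runs[t] <- length(Ns)
    avg$n_runs_triplet[t] <- length(pc)
    if (length(Ns)) { avg$N[t] <- mean(Ns); avg$n[t] <- mean(ns) }
    if (length(pc)) {
      avg$prop_cyclic[t] <- mean(pc); avg$prop_noncyclic[t] <- mean(pn)
    }
    if (length(ch)) avg$chi[t] <- mean(ch)
  }
  structure(list(average = avg, runs = runs, series = series,
                 n_survived = sum(survived), params = params, seed = seed),
            class = "cyclodom_ensemble")
}

#' @export
print.cyclodom_ensemble <- function(x, ...) {
  cat(sprintf("cyclodom_ensemble: %d/%d surviving realizations, %d mutation events\n",
              x$n_survived, length(x$runs), nrow(x$average)))
  w <- steady_state_window(nrow(x$average))
  cat(sprintf("  steady-state (t in [%d, %d]): chi = %.4f\n", w[1], w[2],
              ensemble_chi(x, w)$chi))
  invisible(x)
}

#' Steady-state window of a run
#'
#' Default convention: the last `frac` (5 percent) of the mutation events.
#'
#' @param t_mut_max total mutation events.
#' @param frac window fraction at the end of the run.
#' @return `c(lo, hi)` in mutation events.
#' @export
steady_state_window <- function(t_mut_max, frac = 0.05) {
  c(max(1L, ceiling((1 - frac) * t_mut_max)), t_mut_max)
}

#' Pooled steady-state chi of an ensemble
#'
#' Pools cyclic and non-cyclic dominance triplet counts over all surviving
#' realizations and all snapshots in the window, and returns the pooled
#' `chi` with a bootstrap confidence interval over realizations.
#'
#' @param ens a [run_ensemble()] result.
#' @param window `c(lo, hi)` in mutation events; defaults to
#'   [steady_state_window()] of the run length.
#' @param n_boot bootstrap replicates over realizations.
#' @param conf confidence level.
#' @return list: `chi`, `ci` (length 2), `n_cyclic`, `n_noncyclic`.
#' @export
ensemble_chi <- function(ens, window = NULL, n_boot = 200L, conf = 0.95) {
  stopifnot(inherits(ens, "cyclodom_ensemble"))
  if (is.null(window)) window <- steady_state_window(nrow(ens$average))
  survived <- !vapply(ens$runs, function(s) s$extinct, logical(1))
  per_run <- lapply(which(survived), function(r) {
    ts <- ens$series[[r]]
    sel <- ts$t_mut >= window[1] & ts$t_mut <= window[2] & !is.na(ts$cyclic)
    c(cyc = sum(ts$cyclic[sel]), non = sum(ts$noncyclic[sel]))
  })
  cyc <- sum(vapply(per_run, `[[`, numeric(1), "cyc"))
  non <- sum(vapply(per_run, `[[`, numeric(1), "non"))
  chi_hat <- if (cyc + non > 0) cyc / (cyc + non) else NA_real_
  ci <- c(NA_real_, NA_real_)
  if (length(per_run) > 1 && cyc + non > 0) {
    boots <- vapply(seq_len(n_boot), function(b) {
      pick <- sample(length(per_run), replace = TRUE)
      bc <- sum(vapply(per_run[pick], `[[`, numeric(1), "cyc"))
      bn <- sum(vapply(per_run[pick], `[[`, numeric(1), "non"))
      if (bc + bn > 0) bc / (bc + bn) else NA_real_
    }, numeric(1))
    ci <- unname(quantile(boots, c((1 - conf) / 2, 1 - (1 - conf) / 2), na.rm = TRUE))
  }
  list(chi = chi_hat, ci = ci, n_cyclic = cyc, n_noncyclic = non)
}

#' Steady-state chi across baseline death rates
#'
#' Runs one ensemble per `alpha` and tabulates the pooled steady-state chi
#' with bootstrap confidence intervals, alongside the three reference
#' fractions: the maximizer genealogy (1/6), the random payoff matrix
#' (1/13) and the minimizer genealogy (< 0.001).
#'
#' @param alphas vector of baseline competition death rates.
#' @param params template [model_params()]; its `alpha` is replaced.
#' @param t_mut_max,n_realizations,seed per-ensemble settings.
#' @param window steady-state window; default last 5 percent.
#' @param ... passed to [run_ensemble()].
#' @return data.frame: `alpha`, `chi`, `ci_lo`, `ci_hi`, `n_cyclic`,
#'   `n_noncyclic`, `n_survived`; attribute `references` holds the
#'   reference fractions.
#' @export
alpha_sweep <- function(alphas, params = model_params(), t_mut_max,
                        n_realizations, seed = 1, window = NULL, ...) {
  if (!length(alphas)) stop("alpha_sweep requires a non-empty alphas vector")
  rows <- lapply(seq_along(alphas), function(ai) {
    p <- model_params(params$lambda_b, params$lambda_d, alphas[ai],
                      params$mu, params$sigma)
    ens <- run_ensemble(p, t_mut_max, n_realizations,
                        seed = seed + 1000L * ai, ...)
    cs <- ensemble_chi(ens, window)
    data.frame(alpha = alphas[ai], chi = cs$chi, ci_lo = cs$ci[1],
               ci_hi = cs$ci[2], n_cyclic = cs$n_cyclic,
               n_noncyclic = cs$n_noncyclic, n_survived = ens$n_survived)
  })
  out <- do.call(rbind, rows)
  attr(out, "references") <- c(maximizer_genealogy = 1 / 6,
                               random_matrix = 1 / 13,
                               minimizer_genealogy = 0.001)
  out
}

#' Export a run's artifacts to a directory
#'
#' Writes `timeseries.csv` (per-mutation-event N, n, triplet counts, chi),
#' `lifespans.csv`, `meta.json` (parameters, seed, survival) and, for each
#' surviving dominance triplet at the final snapshot, a Newick genealogy
#' (branch lengths = mutation counts) with JSON sidecar.
#'
#' @param sim a `cyclodom_sim`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
export_run <- function(sim, dir) {
  stopifnot(inherits(sim, "cyclodom_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ts <- triplet_series(sim)
  write.csv(ts, file.path(dir, "timeseries.csv"), row.names = FALSE)
  ls <- track_lifespans(sim)
  write.csv(ls, file.path(dir, "lifespans.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(params = unclass(sim$params), seed = sim$seed, t_mut = sim$t_mut,
         extinct = sim$extinct, events = sim$events,
         wall_time = sim$wall_time),
    file.path(dir, "meta.json"), auto_unbox = TRUE, digits = NA)
  nsnap <- length(sim$snapshots$t_mut)
  if (nsnap > 0 && sim$snapshots$n[nsnap] >= 3) {
    A <- sim$snapshots$A[[nsnap]]; ids <- sim$snapshots$ids[[nsnap]]
    tt <- triplet_table(A, ids)
    tt <- tt[tt$code != 0L, , drop = FALSE]
    for (q in seq_len(nrow(tt))) {
      trip <- c(tt$a[q], tt$b[q], tt$c[q])
      g <- extract_genealogy(sim$genealogy, trip)
      lv <- attr(g, "leaves")
      write_genealogy(g, file.path(dir, sprintf("genealogy_%d_%d_%d.nwk",
                                                trip[1], trip[2], trip[3])),
                      labels = as.character(lv))
    }
  }
  invisible(dir)
}
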