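# Stochastic individual-based simulation layer.

#' Initial population state
#'
#' The run starts from a single type whose self-payoff is drawn from
#' `Normal(log(1000), init_sd)`. Its initial abundance defaults to the
#' deterministic one-type equilibrium
#' `round((lambda_b - lambda_d) / (alpha + exp(-A11)))`, which avoids early
#' stochastic extinctions dominating small-`alpha` comparisons; pass
#' `initial_abundance = 1` (or any positive integer) for invasion-style
#' starts.
#'
#' @param params a [model_params()].
#' @param initial_abundance `"equilibrium"` (default) or a positive integer.
#' @param init_mean,init_sd mean and sd of the founder's self-payoff draw.
#' @return list with `m` (a [payoff_matrix()]), `x` (named abundance
#'   vector), `t_mut = 0`, `wall_time = 0` and an empty `genealogy` log.
#' @export
initial_state <- function(params, initial_abundance = "equilibrium",
                          init_mean = log(1000), init_sd = 1) {
  stopifnot(inherits(params, "model_params"))
  A11 <- rnorm(1, init_mean, init_sd)
  m <- payoff_matrix(matrix(A11, 1, 1), type_ids = 0L)
  x0 <- if (identical(initial_abundance, "equilibrium")) {
    max(1, round((params$lambda_b - params$lambda_d) /
                   competition_death_rate(A11, params$alpha)))
  } else {
    v <- as.integer(initial_abundance)
    if (is.na(v) || v < 1L) stop("initial_abundance must be 'equilibrium' or a positive integer")
    v
  }
  list(m = m, x = setNames(as.numeric(x0), "0"), t_mut = 0L, wall_time = 0,
       genealogy = data.frame(t_mut = integer(), parent = integer(), child = integer()))
}

#' Reaction rate table for a population state
#'
#' Per-type rates of the four reactions. Birth is listed as a single rate
#' `lambda_b * x_i` per type (the mutant/clonal split `mu : 1 - mu` is
#' resolved when the birth fires). Competition death of an i-individual has
#' total rate `x_i * (sum_j d_ij x_j - d_ii)`: ordered victim-killer pairs
#' among distinct individuals, so an individual cannot kill itself.
#'
#' @param state a state as returned by [initial_state()] or [sim_step()].
#' @param params a [model_params()].
#' @return data.frame with columns `id`, `birth`, `bg_death`, `competition`.
#' @export
event_rates <- function(state, params) {
  stopifnot(inherits(params, "model_params"))
  ids <- state$m$type_ids
  if (length(ids) == 0L)
    return(data.frame(id = integer(), birth = numeric(),
                      bg_death = numeric(), competition = numeric()))
  x <- as.numeric(state$x[as.character(ids)])
  d <- matrix(competition_death_rate(state$m$A, params$alpha),
              nrow(state$m$A), ncol(state$m$A))
  S <- as.vector(d %*% x)
  data.frame(id = ids,
             birth = params$lambda_b * x,
             bg_death = params$lambda_d * x,
             competition = pmax(x * (S - diag(d)), 0))
}

#' Advance the population by one reaction (reference implementation)
#'
#' Samples one reaction with probability proportional to its rate plus an
#' exponential waiting time, and applies it. This R-level step is the
#' readable reference for the compiled run loop used by
#' [simulate_population()]; it is exact but slow, intended for inspection
#' and unit tests at tiny scales.
#'
#' @inheritParams event_rates
#' @return the updated state (fields as in [initial_state()]).
#' @export
sim_step <- function(state, params) {
  rates <- event_rates(state, params)
  if (nrow(rates) == 0L || sum(state$x) <= 0) stop("population is extinct")
  ids <- rates$id
  totals <- c(sum(rates$birth), sum(rates$bg_death), sum(rates$competition))
  total <- sum(totals)
  state$wall_time <- state$wall_time + rexp(1, total)
  u <- runif(1) * total
  pick <- function(w) ids[sample.int(length(w), 1L, prob = w)]
  key <- function(id) as.character(id)
  if (u < totals[1]) { # birth
    i <- pick(rates$birth)
    if (runif(1) < params$mu) {
      child <- state$m$next_id
      state$m <- mutate_payoffs(state$m, i, params$sigma)
      state$x[key(child)] <- 1
      state$t_mut <- state$t_mut + 1L
      state$genealogy <- rbind(state$genealogy,
                               data.frame(t_mut = state$t_mut, parent = i, child = child))
    } else {
      state$x[key(i)] <- state$x[key(i)] + 1
    }
  } else {
    i <- if (u < totals[1] + totals[2]) pick(rates$bg_death) else pick(rates$competition)
    state$x[key(i)] <- state$x[key(i)] - 1
    if (state$x[key(i)] <= 0) {
      state$m <- remove_types(state$m, i)
      state$x <- state$x[names(state$x) != key(i)]
    }
  }
  state
}

#' Simulate the evolving community
#'
#' Runs the exact Gillespie dynamics until `t_mut_max` mutation events have
#' occurred (the model's clock counts mutation events), the population goes
#' extinct, or `max_events` single reactions have fired. A snapshot of
#' `(t_mut, N, n, type IDs, payoff matrix)` is recorded at every mutation
#' event, along with the genealogy log `(t_mut, parent, child)` for every
#' mutant ever born.
#'
#' @param params a [model_params()].
#' @param t_mut_max number of mutation events to simulate (>= 1 unless
#'   `mu = 0`, in which case only `max_events` can stop the run).
#' @param seed optional integer; when given, `set.seed(seed)` is called so
#'   the run is bit-reproducible.
#' @param initial_abundance see [initial_state()].
#' @param init_mean,init_sd founder payoff draw, see [initial_state()].
#' @param max_events cap on single reactions (default `Inf`; required
#'   finite when `mu = 0`).
#' @param trace_thin record `(event, T, N)` every `trace_thin` reactions
#'   (0 = no trace); used for stationarity diagnostics.
#' @return an object of class `cyclodom_sim` with fields `params`, `seed`,
#'   `snapshots` (list: `t_mut`, `N`, `n`, `wall_time`, `ids`, `A`),
#'   `genealogy`, `trace`, `final` (list with `m`, `x`), `extinct`,
#'   `t_mut`, `wall_time`, `events`.
#' @examples
#' sim <- simulate_population(model_params(alpha = 1e-2, mu = 1e-2),
#'                            t_mut_max = 20, seed = 1)
#' summary(sim)
#' @export
simulate_population <- function(params, t_mut_max, seed = NULL,
                                initial_abundance = "equilibrium",
                                init_mean = log(1000), init_sd = 1,
                                max_events = Inf, trace_thin = 0L) {
  stopifnot(inherits(params, "model_params"))
  if (params$mu == 0 && !is.finite(max_events))
    stop("with mu = 0 the mutation clock never advances; supply a finite max_events")
  if (params$mu > 0 && t_mut_max < 1) stop("t_mut_max must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  st <- initial_state(params, initial_abundance, init_mean, init_sd)
  res <- run_gillespie_cpp(st$m$A, st$m$type_ids, unname(st$x),
                           params$lambda_b, params$lambda_d, params$alpha,
                           params$mu, params$sigma,
                           as.integer(t_mut_max),
                           if (is.finite(max_events)) max_events else 1e18,
                           st$m$next_id, as.integer(trace_thin), 700)
  final_m <- payoff_matrix(res$final$A, res$final$ids, next_id = res$final$next_id)
  structure(list(
    params = params, seed = seed,
    snapshots = list(t_mut = res$snap_t_mut, N = res$snap_N, n = res$snap_n,
                     wall_time = res$snap_T, ids = res$snap_ids, A = res$snap_A),
    genealogy = res$genealogy,
    trace = res$trace,
    final = list(m = final_m,
                 x = setNames(res$final$x, res$final$ids)),
    extinct = res$extinct, t_mut = res$t_mut,
    wall_time = res$wall_time, events = res$events), class = "cyclodom_sim")
}

#' @export
print.cyclodom_sim <- function(x, ...) {
  cat(sprintf("cyclodom_sim: %d mutation events, %.0f reactions%s\n",
              x$t_mut, x$events, if (x$extinct) " (EXTINCT)" else ""))
  cat(sprintf("  final: N = %.0f, n = %d types; wall time T = %.1f\n",
              sum(x$final$x), length(x$final$x), x$wall_time))
  invisible(x)
}

#' @export
summary.cyclodom_sim <- function(object, ...) {
  s <- object$snapshots
  out <- list(t_mut = object$t_mut, extinct = object$extinct,
              events = object$events,
              final_N = sum(object$final$x), final_n = length(object$final$x),
              mean_N = if (length(s$N)) mean(s$N) else NA_real_,
              mean_n = if (length(s$n)) mean(s$n) else NA_real_)
  class(out) <- "summary.cyclodom_sim"
  out
}

#' @export
print.summary.cyclodom_sim <- function(x, ...) {
  cat(sprintf("mutation events: %d%s, reactions: %.0f\n", x$t_mut,
              if (x$extinct) " (extinct)" else "", x$events))
  cat(sprintf("final N = %.0f, final n = %d; snapshot means: <N> = %.1f, <n> = %.2f\n",
              x$final_N, x$final_n, x$mean_N, x$mean_n))
  invisible(x)
}

#' @export
plot.cyclodom_sim <- function(x, ...) {
  s <- x$snapshots
  if (!length(s$t_mut)) {
    warning("no mutation-event snapshots to plot")
    return(invisible(x))
  }
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::plot(s$t_mut, s$N, type = "l", xlab = "mutation events t",
                 ylab = "population size N", ...)
  graphics::plot(s$t_mut, s$n, type = "s", xlab = "mutation events t",
                 ylab = "diversity n", ...)
  invisible(x)
}
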