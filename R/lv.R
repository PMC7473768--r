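# Deterministic competitive Lotka-Volterra layer. Its job is verification:
# the pairwise classifier must agree with the asymptotic outcome of the
# two-type ODE, and equilibrium abundances anchor the stochastic simulator.

#' Competitive Lotka-Volterra system
#'
#' Describes the deterministic dynamics
#' `dx_i/dT = (lambda_b - lambda_d) x_i - x_i * sum_j d_ij x_j`
#' with competition death rates `d_ij > 0`.
#'
#' @param d square matrix of competition death rates (all > 0), e.g. from
#'   [competition_death_rate()] applied to a payoff matrix.
#' @param lambda_b,lambda_d per-capita birth and background death rates,
#'   `lambda_b > lambda_d > 0`.
#' @return an object of class `lv_system`.
#' @export
lv_system <- function(d, lambda_b = 0.9, lambda_d = 0.4) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d)) stop("d must be square")
  if (!all(is.finite(d)) || any(d <= 0)) stop("all competition rates must be positive")
  if (lambda_b <= lambda_d || lambda_d <= 0) stop("need lambda_b > lambda_d > 0")
  structure(list(d = d, lambda_b = lambda_b, lambda_d = lambda_d), class = "lv_system")
}

#' Right-hand side of the competitive LV equation
#'
#' @param x non-negative abundance vector (one entry per type).
#' @param sys an [lv_system()].
#' @return vector of time derivatives `dx/dT`.
#' @examples
#' sys <- lv_system(matrix(0.001005), 0.9, 0.4)
#' lv_rhs((0.9 - 0.4) / 0.001005, sys)  # ~0: one-type equilibrium
#' @export
lv_rhs <- function(x, sys) {
  stopifnot(inherits(sys, "lv_system"))
  if (length(x) != nrow(sys$d)) stop("dimension mismatch between x and d")
  if (any(!is.finite(x)) || any(x < 0)) stop("abundances must be finite and non-negative")
  (sys$lambda_b - sys$lambda_d) * x - x * as.vector(sys$d %*% x)
}

#' Integrate the competitive LV dynamics
#'
#' Adaptive integration (via \pkg{deSolve}'s `lsoda`) until `horizon`, with
#' abundances clipped at zero. Types whose density falls below
#' `extinct_tol` times the total density at the end are reported as
#' extinct. If the terminal state is not yet an equilibrium (relative
#' derivative above `tol`), the trajectory is still returned with
#' `converged = FALSE`.
#'
#' @param sys an [lv_system()].
#' @param x0 initial abundances.
#' @param horizon integration time (> 0).
#' @param tol relative-derivative tolerance used to declare equilibrium.
#' @param extinct_tol density fraction below which a type counts as extinct.
#' @param n_out number of output time points.
#' @return list with `times`, `trajectory` (matrix, one column per type),
#'   `final`, `converged`, `extinct` (indices).
#' @export
integrate_lv <- function(sys, x0, horizon = 1e4, tol = 1e-8,
                         extinct_tol = 1e-9, n_out = 200L) {
  stopifnot(inherits(sys, "lv_system"), horizon > 0)
  if (length(x0) != nrow(sys$d)) stop("dimension mismatch")
  rhs <- function(t, x, parms) list(lv_rhs(pmax(x, 0), sys))
  times <- seq(0, horizon, length.out = n_out)
  sol <- deSolve::lsoda(y = as.numeric(x0), times = times, func = rhs,
                        parms = NULL, rtol = tol, atol = tol * max(sum(x0), 1))
  traj <- pmax(sol[, -1, drop = FALSE], 0)
  final <- unname(traj[nrow(traj), ])
  deriv <- lv_rhs(final, sys)
  converged <- sqrt(sum(deriv^2)) <= 100 * tol * max(sum(final), 1)
  extinct <- which(final < extinct_tol * max(sum(final), .Machine$double.eps))
  list(times = sol[, 1], trajectory = traj, final = final,
       converged = converged, extinct = extinct)
}

#' Two-type outcome by ODE integration
#'
#' Independent oracle for [classify_pair()]: builds the competition rates
#' from the four payoffs and decides the asymptotic outcome of the
#' two-type LV dynamics by numerical integration. If the system has a
#' positive interior fixed point (`d x* = (lambda_b - lambda_d) 1`,
#' `x* > 0`), trajectories started from small asymmetric perturbations of
#' `x*` reveal its stability: both returning means coexistence, divergence
#' to the two opposite fixations means bistability. Without a positive
#' interior point, integration from initial fractions 0.99, 0.5 and 0.01
#' of the carrying capacities identifies the dominant type. Ambiguous
#' numerical outcomes (near-degenerate payoffs) yield `"indeterminate"`
#' rather than a silent class.
#'
#' @inheritParams classify_pair
#' @param params a [model_params()] (supplies `lambda_b`, `lambda_d`,
#'   `alpha`).
#' @param horizon integration time per start.
#' @return one of the four pair classes, or `"indeterminate"`.
#' @export
two_type_outcome_by_ode <- function(Aii, Aij, Aji, Ajj, params = model_params(),
                                    horizon = 2e4) {
  stopifnot(inherits(params, "model_params"))
  d <- matrix(competition_death_rate(c(Aii, Aji, Aij, Ajj), params$alpha), 2, 2)
  sys <- lv_system(d, params$lambda_b, params$lambda_d)
  growth <- params$lambda_b - params$lambda_d
  K <- growth / diag(d)  # single-type carrying capacities
  xstar <- tryCatch(solve(d, rep(growth, 2)), error = function(e) c(-1, -1))
  settle <- function(x0) {
    res <- integrate_lv(sys, x0, horizon = horizon)
    if (!res$converged) return("?")
    alive <- setdiff(1:2, res$extinct)
    if (length(alive) == 2L) {
      if (max(abs(res$final - xstar) / pmax(xstar, 1e-300)) < 0.05) "12" else "?"
    } else paste(alive, collapse = "")
  }
  if (all(is.finite(xstar)) && all(xstar > 0)) {
    # interior fixed point exists: probe its stability by integration
    eps <- 0.02
    o1 <- settle(xstar * c(1 + eps, 1 - eps))
    o2 <- settle(xstar * c(1 - eps, 1 + eps))
    if (o1 == "12" && o2 == "12") return("coexist")
    if (o1 == "1" && o2 == "2") return("bistable")
    return("indeterminate")
  }
  outcomes <- vapply(c(0.99, 0.5, 0.01), function(f) {
    settle(c(f * K[1], (1 - f) * K[2]))
  }, character(1))
  if (all(outcomes == "1")) "dom_first"
  else if (all(outcomes == "2")) "dom_second"
  else "indeterminate"
}
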