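#' Model parameters
#'
#' Bundle of the demographic and mutational parameters of the model.
#' Individuals of every type share the per-capita birth rate `lambda_b` and
#' background death rate `lambda_d`; competition kills an individual of
#' type i through an encounter with an individual of type j at rate
#' `d_ij = alpha + exp(-A_ij)` per ordered pair. A birth is a mutant with
#' probability `mu`, in which case the offspring's payoffs equal the
#' parent's plus independent `Normal(0, sigma^2)` noise.
#'
#' The population collapses whenever `lambda_b <= lambda_d`, so that
#' regime is rejected.
#'
#' @param lambda_b per-capita birth rate (> lambda_d).
#' @param lambda_d per-capita background death rate (> 0).
#' @param alpha baseline competition death rate (> 0); small `alpha` means
#'   a rich environment and a large saturated population near
#'   `(lambda_b - lambda_d) / alpha`.
#' @param mu mutation probability per birth, in `[0, 1]`.
#' @param sigma standard deviation of the payoff mutation noise (> 0).
#' @return an object of class `model_params`.
#' @examples
#' model_params(alpha = 1e-3, mu = 1e-3)
#' @export
model_params <- function(lambda_b = 0.9, lambda_d = 0.4, alpha = 5e-6,
                         mu = 1e-5, sigma = 1) {
  p <- list(lambda_b = lambda_b, lambda_d = lambda_d, alpha = alpha,
            mu = mu, sigma = sigma)
  if (!all(vapply(p, function(v) is.numeric(v) && length(v) == 1L && is.finite(v), logical(1))))
    stop("all parameters must be finite numeric scalars")
  if (lambda_d <= 0) stop("lambda_d must be positive")
  if (lambda_b <= lambda_d) stop("lambda_b must exceed lambda_d (otherwise the population collapses)")
  if (alpha <= 0) stop("alpha must be positive")
  if (mu < 0 || mu > 1) stop("mu must lie in [0, 1]")
  if (sigma <= 0) stop("sigma must be positive")
  structure(p, class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat(sprintf(
    "model_params: lambda_b=%g lambda_d=%g alpha=%g mu=%g sigma=%g\n",
    x$lambda_b, x$lambda_d, x$alpha, x$mu, x$sigma))
  invisible(x)
}
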