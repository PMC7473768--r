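# Vectorized triplet classification over many 3x3 matrices at once.
# Entry layout: one matrix per row, columns in column-major order
# (A11, A21, A31, A12, A22, A32, A13, A23, A33).

#' Classify many 3x3 payoff matrices at once
#'
#' Vectorized version of [classify_triplet()] for Monte-Carlo work. Each row
#' of `E` holds one 3x3 matrix in column-major order. Ties are not checked
#' here (they have probability zero for the continuous ensembles this is
#' used with); a tied comparison falls into an arbitrary class.
#'
#' @param E numeric matrix with 9 columns, one 3x3 payoff matrix per row in
#'   column-major order.
#' @return integer vector, one code per row: 0 mixed, 1 cyclic, 2 noncyclic.
#' @examples
#' E <- matrix(rnorm(9000), ncol = 9)
#' table(classify_triplets_bulk(E))
#' @export
classify_triplets_bulk <- function(E) {
  E <- as.matrix(E)
  if (ncol(E) != 9L) stop("E must have 9 columns (3x3 matrices, column-major)")
  a11 <- E[, 1]; a21 <- E[, 2]; a31 <- E[, 3]
  a12 <- E[, 4]; a22 <- E[, 5]; a32 <- E[, 6]
  a13 <- E[, 7]; a23 <- E[, 8]; a33 <- E[, 9]
  # pair (1,2): column 1 compares A11 vs A21, column 2 compares A12 vs A22
  s12a <- a11 > a21; s12b <- a12 > a22; dom12 <- s12a == s12b
  s13a <- a11 > a31; s13b <- a13 > a33; dom13 <- s13a == s13b
  s23a <- a22 > a32; s23b <- a23 > a33; dom23 <- s23a == s23b
  alldom <- dom12 & dom13 & dom23
  # out-degree of each node in the beats-tournament (only valid when alldom)
  o1 <- s12a + s13a
  o2 <- (!s12a) + s23a
  o3 <- (!s13a) + (!s23a)
  cyc <- alldom & o1 == 1L & o2 == 1L & o3 == 1L
  out <- integer(nrow(E))
  out[alldom] <- 2L
  out[cyc] <- 1L
  out
}

# chi with binomial standard error from bulk classification codes
chi_from_codes <- function(codes) {
  n_cyc <- sum(codes == 1L)
  n_dom <- n_cyc + sum(codes == 2L)
  if (n_dom == 0L)
    return(list(chi = NA_real_, se = NA_real_, n_cyclic = 0L, n_dominance = 0L))
  chi <- n_cyc / n_dom
  list(chi = chi, se = sqrt(chi * (1 - chi) / n_dom),
       n_cyclic = n_cyc, n_dominance = n_dom)
}
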