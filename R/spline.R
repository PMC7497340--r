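# Linear-spline basis on the GDD axis and covariance-function reconstruction.

#' Linear-spline covariables for one GDD value
#'
#' For a record at thermal time `gdd_s` falling between knots k and k+1 the
#' covariable at knot k is `(GDD_{k+1} - gdd_s) / (GDD_{k+1} - GDD_k)`, the
#' covariable at knot k+1 is its complement, and all other knots are exactly
#' zero. At a knot the vector is an indicator. No extrapolation outside the
#' knot range is supported.
#'
#' @param gdd_s cumulative GDD of the record (scalar).
#' @param knots strictly increasing vector of knot GDDs (m >= 2).
#' @return Numeric vector of length `length(knots)`; non-negative, sums to 1,
#'   with at most two nonzero entries.
#' @examples
#' spline_covariables(816, c(524, 816, 1501))  # c(0, 1, 0)
#' spline_covariables(670, c(524, 816, 1501))  # c(0.5, 0.5, 0)
#' @export
spline_covariables <- function(gdd_s, knots) {
  if (length(knots) < 2 || is.unsorted(knots, strictly = TRUE))
    stop("knots must be a strictly increasing vector of length >= 2",
         call. = FALSE)
  if (length(gdd_s) != 1 || !is.finite(gdd_s))
    stop("gdd_s must be a finite scalar", call. = FALSE)
  m <- length(knots)
  if (gdd_s < knots[1] || gdd_s > knots[m])
    stop(sprintf("GDD %g outside knot range [%g, %g]; no extrapolation",
                 gdd_s, knots[1], knots[m]), call. = FALSE)
  z <- numeric(m)
  if (gdd_s == knots[m]) {
    z[m] <- 1
    return(z)
  }
  k <- findInterval(gdd_s, knots)
  z[k] <- (knots[k + 1] - gdd_s) / (knots[k + 1] - knots[k])
  z[k + 1] <- 1 - z[k]
  z
}

#' Spline covariable matrix for a vector of GDDs
#'
#' @param gdds vector of cumulative GDD values.
#' @param knots strictly increasing knot GDDs.
#' @return Matrix with one row per entry of `gdds` and one column per knot.
#' @export
spline_basis <- function(gdds, knots) {
  t(vapply(gdds, spline_covariables, numeric(length(knots)), knots = knots))
}

#' Genetic (co)variance between two time points from spline coefficients
#'
#' Given the m x m covariance of the spline coefficients, the genetic
#' covariance between thermal times t and s is the quadratic/bilinear form
#' `z(t)' Sigma_a z(s)`; with `t == s` it is the genetic variance at t. At
#' knot pairs this returns the entries of `Sigma_a` exactly.
#'
#' @param Sigma_a m x m coefficient covariance matrix.
#' @param knots knot GDD vector (length m).
#' @param t,s cumulative GDD time points (default `s = t`).
#' @return Covariance (numeric scalar).
#' @export
reconstruct_covariance <- function(Sigma_a, knots, t, s = t) {
  Sigma_a <- as.matrix(Sigma_a)
  if (nrow(Sigma_a) != length(knots))
    stop("Sigma_a dimension must equal the number of knots", call. = FALSE)
  zt <- spline_covariables(t, knots)
  zs <- spline_covariables(s, knots)
  drop(zt %*% Sigma_a %*% zs)
}

#' Reconstructed covariance (or correlation) matrix over a set of time points
#'
#' @param Sigma_a m x m coefficient covariance matrix.
#' @param knots knot GDD vector.
#' @param gdds time points at which to evaluate.
#' @param correlation return the correlation matrix instead of covariances.
#' @return Square matrix over `gdds` (dimnames carry the GDD values).
#' @export
reconstruct_covariance_grid <- function(Sigma_a, knots, gdds,
                                        correlation = FALSE) {
  Z <- spline_basis(gdds, knots)
  V <- Z %*% as.matrix(Sigma_a) %*% t(Z)
  if (correlation) V <- stats::cov2cor(V)
  dimnames(V) <- list(gdds, gdds)
  V
}
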