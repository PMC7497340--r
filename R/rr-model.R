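# Random regression on linear splines over the GDD axis.

#' Fit a linear-spline random-regression model to VI trajectories
#'
#' Model for repeated plot-level records over the growing season:
#' `y = Xb + Z1 a + Z2 pe + e`, where the fixed effects are
#' replicate-by-time cell means, `a` holds one spline coefficient per knot
#' per hybrid with covariance `Sigma_a (x) G`, `pe` holds one coefficient
#' vector per plot (permanent environment, covariance `Sigma_pe (x) I`),
#' and residuals are independent with a separate variance per time point.
#' Estimation is EM-REML in the eigenbasis of `G`; the permanent-environment
#' term is absorbed into the per-plot residual covariance and recovered in
#' the E-step, so each iteration costs O(hybrids). The restricted
#' log-likelihood is monotone non-decreasing over iterations.
#'
#' The fit requires complete balanced data: every plot recorded at every
#' time point and every hybrid present once per replicate. All record GDDs
#' must lie inside the knot range (no extrapolation).
#'
#' @param pheno long data.frame with columns `plot_id`, `hybrid_id`,
#'   `replicate`, `gdd`, `value`.
#' @param knots strictly increasing knot GDD vector (m >= 2, m no larger
#'   than the number of distinct time points).
#' @param G relationship matrix with hybrid ids as dimnames.
#' @param tol,par_tol,max_iter convergence controls.
#' @return An object of class `rr_gblup`: `Sigma_a` (m x m), `Sigma_pe`
#'   (m x m), `resid_vars` (per time point), `a_hat` (hybrids x m),
#'   `pe_hat` (plots x m), `mu_hat` (replicate-by-time cell means),
#'   `knots`, `time_gdds`, `loglik`, `loglik_trace`, `converged`,
#'   `n_iter`, `n_bend`, `G`.
#' @export
fit_random_regression <- function(pheno, knots, G, tol = 1e-8,
                                  par_tol = 1e-6, max_iter = 500L) {
  check_columns(pheno, c("plot_id", "hybrid_id", "replicate", "gdd",
                         "value"), "longitudinal table")
  hybrids <- rownames(G)
  if (!all(pheno$hybrid_id %in% hybrids))
    stop("phenotypes contain hybrids absent from G", call. = FALSE)
  times <- sort(unique(pheno$gdd))
  n_t <- length(times)
  m <- length(knots)
  if (m < 2) stop("need at least 2 knots", call. = FALSE)
  if (m > n_t)
    stop(sprintf("identifiability error: %d knots exceed %d distinct time points",
                 m, n_t), call. = FALSE)
  reps <- sort(unique(pheno$replicate))
  if (length(reps) < 2)
    stop("every time point needs at least two replicates", call. = FALSE)
  key <- paste(pheno$plot_id, pheno$gdd)
  if (anyDuplicated(key))
    stop("duplicate (plot, time) records", call. = FALSE)
  plots <- unique(pheno[, c("plot_id", "hybrid_id", "replicate")])
  tab <- table(factor(plots$hybrid_id, levels = hybrids),
               factor(plots$replicate, levels = reps))
  cnt <- table(factor(pheno$plot_id), factor(pheno$gdd, levels = times))
  if (!all(tab == 1) || !all(cnt == 1))
    stop("random regression requires complete balanced plot x time data",
         call. = FALSE)

  Phi <- spline_basis(times, knots)      # errors on out-of-range GDDs
  # response matrix: hybrids x (reps * times), time within replicate
  Y <- matrix(NA_real_, length(hybrids), length(reps) * n_t,
              dimnames = list(hybrids, NULL))
  hi <- match(pheno$hybrid_id, hybrids)
  ri <- match(pheno$replicate, reps)
  ti <- match(pheno$gdd, times)
  Y[cbind(hi, (ri - 1) * n_t + ti)] <- pheno$value
  plot_ids <- matrix(NA_character_, length(hybrids), length(reps))
  plot_ids[cbind(hi, ri)] <- pheno$plot_id

  v_t <- tapply(pheno$value, ti, stats::var)
  v_bar <- mean(v_t)
  Sg0 <- diag(v_bar / 4, m) + v_bar / 20
  Spe0 <- diag(v_bar / 4, m) + v_bar / 20
  fit <- balanced_em_reml(Y, G, Phi = Phi, model = "rr",
                          Sigma_a = Sg0,
                          R_par = list(Sigma_pe = Spe0,
                                       resid_vars = pmax(v_t / 2, 1e-10)),
                          tol = tol, par_tol = par_tol, max_iter = max_iter)
  A <- fit$a_hat
  rownames(A) <- hybrids
  pe <- do.call(rbind, fit$pe_hat)
  rownames(pe) <- as.vector(plot_ids)
  mu <- matrix(fit$mu_hat, length(reps), n_t, byrow = TRUE,
               dimnames = list(reps, times))
  rv <- fit$R_par$resid_vars
  names(rv) <- times
  structure(list(Sigma_a = fit$Sigma_a, Sigma_pe = fit$R_par$Sigma_pe,
                 resid_vars = rv, a_hat = A, pe_hat = pe, mu_hat = mu,
                 knots = knots, time_gdds = times, loglik = fit$loglik,
                 loglik_trace = fit$loglik_trace, converged = fit$converged,
                 n_iter = fit$n_iter, n_bend = fit$n_bend, G = G),
            class = "rr_gblup")
}

#' Genetic growth curves from a random-regression fit
#'
#' Evaluates each hybrid's estimated genetic trajectory
#' `sum_k z_k(t) a_hat_k` on a GDD grid (piecewise linear between knots).
#' With `groups`, per-group mean curves are returned instead (e.g. high-
#' versus low-yielding hybrids).
#'
#' @param fit an `rr_gblup` fit.
#' @param gdd_grid GDD values inside the knot range.
#' @param groups optional named list of hybrid-id vectors.
#' @return data.frame with columns `hybrid` (or `group`), `gdd`,
#'   `genetic_value`.
#' @export
genetic_curves <- function(fit, gdd_grid, groups = NULL) {
  Z <- spline_basis(gdd_grid, fit$knots)
  A <- fit$a_hat
  if (is.null(groups)) {
    vals <- A %*% t(Z)
    out <- data.frame(hybrid = rep(rownames(A), length(gdd_grid)),
                      gdd = rep(gdd_grid, each = nrow(A)),
                      genetic_value = as.vector(vals),
                      stringsAsFactors = FALSE)
    return(out)
  }
  if (is.null(names(groups)) || any(names(groups) == ""))
    stop("groups must be a named list", call. = FALSE)
  rows <- lapply(names(groups), function(gn) {
    ids <- groups[[gn]]
    if (length(ids) == 0)
      stop(sprintf("group '%s' is empty", gn), call. = FALSE)
    if (!all(ids %in% rownames(A)))
      stop(sprintf("group '%s' contains unknown hybrids", gn), call. = FALSE)
    curve <- colMeans(A[ids, , drop = FALSE] %*% t(Z))
    data.frame(group = gn, gdd = gdd_grid, genetic_value = curve,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
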