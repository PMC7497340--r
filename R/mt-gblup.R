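# Bivariate (multi-trait) GBLUP with unstructured 2x2 genetic and residual
# covariance matrices.

#' Fit a bivariate GBLUP model by EM-REML
#'
#' Joint model for two plot-level traits with genetic effects
#' `vec(A) ~ N(0, Sigma_g (x) G)` (unstructured 2x2 genetic covariance) and
#' plot residuals `~ N(0, Sigma_e)` for jointly recorded plots; plots
#' carrying only one trait contribute its marginal residual variance, so
#' per-trait record sets may differ (e.g. masked hybrids in
#' cross-validation, which keep their secondary-trait records). Fixed
#' effects are replicate-by-trait cell means. Fully recorded balanced data
#' are fitted in the eigenbasis of `G`; any missingness falls back to the
#' mixed-model-equation engine, whose random effect spans every hybrid in
#' `G` so masked hybrids receive predictions directly. Interim non-positive-
#' definite covariance estimates are bent (eigenvalues floored) and counted.
#'
#' @param pheno data.frame with columns `plot_id`, `hybrid_id`, `replicate`
#'   and the two trait columns; `NA` marks an unrecorded trait on a plot.
#' @param traits length-2 character vector naming the trait columns.
#' @param G relationship matrix with hybrid ids as dimnames.
#' @param tol,par_tol,max_iter convergence controls as in [fit_st_gblup()].
#' @param start optional list with starting `Sigma_g` and `Sigma_e` (2x2),
#'   e.g. to warm-start cross-validation folds.
#' @return An object of class `mt_gblup`: `Sigma_g`, `Sigma_e`, `r_g`,
#'   `r_e`, `a_hat` (hybrids x 2), `loglik`, `loglik_trace`, `converged`,
#'   `n_iter`, `n_bend`, `method`, `G`.
#' @export
fit_mt_gblup <- function(pheno, traits, G, tol = 1e-8, par_tol = 1e-6,
                         max_iter = 500L, start = NULL) {
  stopifnot(length(traits) == 2)
  check_columns(pheno, c("plot_id", "hybrid_id", "replicate", traits),
                "phenotype table")
  hybrids <- rownames(G)
  if (!all(pheno$hybrid_id %in% hybrids))
    stop("phenotypes contain hybrids absent from G", call. = FALSE)
  y1 <- pheno[[traits[1]]]
  y2 <- pheno[[traits[2]]]
  v1 <- stats::var(y1, na.rm = TRUE)
  v2 <- stats::var(y2, na.rm = TRUE)
  cov_start <- 0.5 * sqrt(v1 * v2) * 0.1
  Sg0 <- matrix(c(v1 / 2, cov_start, cov_start, v2 / 2), 2, 2)
  Se0 <- matrix(c(v1 / 2, cov_start, cov_start, v2 / 2), 2, 2)
  if (!is.null(start)) {
    if (!is.null(start$Sigma_g)) Sg0 <- start$Sigma_g
    if (!is.null(start$Sigma_e)) Se0 <- start$Sigma_e
  }

  reps <- sort(unique(pheno$replicate))
  complete <- !is.na(y1) & !is.na(y2)
  tab <- table(factor(pheno$hybrid_id, levels = hybrids),
               factor(pheno$replicate, levels = reps))
  balanced <- all(complete) && length(reps) >= 2 && all(tab == 1)

  if (balanced) {
    # slot order within replicate: (trait1, trait2)
    Y <- matrix(NA_real_, length(hybrids), 2 * length(reps),
                dimnames = list(hybrids, NULL))
    hi <- match(pheno$hybrid_id, hybrids)
    ri <- match(pheno$replicate, reps)
    Y[cbind(hi, (ri - 1) * 2 + 1)] <- y1
    Y[cbind(hi, (ri - 1) * 2 + 2)] <- y2
    fit <- balanced_em_reml(Y, G, Phi = diag(2), model = "mt",
                            Sigma_a = Sg0, R_par = list(Sigma_e = Se0),
                            tol = tol, par_tol = par_tol,
                            max_iter = max_iter)
    Sigma_g <- fit$Sigma_a
    Sigma_e <- fit$R_par$Sigma_e
    A <- fit$a_hat
    rownames(A) <- hybrids
    method <- "em_eigen"
    n_bend <- fit$n_bend
  } else {
    long <- rbind(
      data.frame(plot_id = pheno$plot_id, hybrid_id = pheno$hybrid_id,
                 replicate = pheno$replicate, trait = 1L, value = y1,
                 stringsAsFactors = FALSE),
      data.frame(plot_id = pheno$plot_id, hybrid_id = pheno$hybrid_id,
                 replicate = pheno$replicate, trait = 2L, value = y2,
                 stringsAsFactors = FALSE))
    long <- long[!is.na(long$value), ]
    fit <- general_em_reml(long, G, n_traits = 2L, Sigma_g = Sg0,
                           Sigma_e = Se0, tol = tol, par_tol = par_tol,
                           max_iter = max_iter)
    Sigma_g <- fit$Sigma_g
    Sigma_e <- fit$Sigma_e
    A <- fit$a_hat
    method <- "em_mme"
    n_bend <- fit$n_bend
  }
  colnames(A) <- traits
  dimnames(Sigma_g) <- dimnames(Sigma_e) <- list(traits, traits)
  structure(list(Sigma_g = Sigma_g, Sigma_e = Sigma_e,
                 r_g = genetic_correlation(Sigma_g),
                 r_e = genetic_correlation(Sigma_e),
                 a_hat = A, loglik = fit$loglik,
                 loglik_trace = fit$loglik_trace, converged = fit$converged,
                 n_iter = fit$n_iter, n_bend = n_bend, method = method,
                 G = G, traits = traits),
            class = "mt_gblup")
}

#' Correlation from a 2x2 covariance matrix
#'
#' `sigma_12 / sqrt(sigma_11 * sigma_22)`; used for both genetic and
#' residual correlations of a bivariate fit.
#'
#' @param Sigma 2x2 covariance matrix with positive diagonal.
#' @return Correlation (numeric scalar).
#' @export
genetic_correlation <- function(Sigma) {
  Sigma <- as.matrix(Sigma)
  stopifnot(nrow(Sigma) == 2, ncol(Sigma) == 2)
  if (any(diag(Sigma) <= 0))
    stop("correlation undefined: zero variance on the diagonal",
         call. = FALSE)
  Sigma[1, 2] / sqrt(Sigma[1, 1] * Sigma[2, 2])
}
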