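# Single-trait GBLUP: y = Xb + Za + e, a ~ N(0, sigma_a2 G),
# e ~ N(0, sigma_e2 I), with intercept-plus-replicate fixed effects.

#' Fit a single-trait GBLUP model by EM-REML
#'
#' Estimates the additive and residual variances of
#' `y = Xb + Za + e`, with `a ~ N(0, sigma_a2 G)` over hybrids and i.i.d.
#' residuals, by EM-REML (monotone restricted log-likelihood), and returns
#' the BLUP genetic effects at the estimates. Fixed effects are the
#' replicate means (equivalent to intercept plus replicate). Balanced
#' designs (every phenotyped hybrid observed once per replicate) are fitted
#' in the eigenbasis of `G`; unbalanced data fall back to a mixed-model
#' equation engine. Hybrids present in `G` but without records are allowed
#' and can be predicted afterwards with [predict_genetic_values()].
#'
#' @param pheno data.frame with columns `hybrid_id`, `replicate`, `value`.
#' @param G relationship matrix with hybrid ids as dimnames (positive
#'   definite).
#' @param tol convergence tolerance on the change in restricted
#'   log-likelihood, applied in relative form
#'   (`|delta| < tol * (1 + |loglik|)`).
#' @param par_tol relative parameter-change tolerance.
#' @param max_iter maximum EM iterations; non-convergence is flagged, not an
#'   error.
#' @return An object of class `st_gblup` with elements `sigma_a2`,
#'   `sigma_e2`, `h2`, `a_hat` (named, phenotyped hybrids), `b_hat`,
#'   `loglik`, `loglik_trace`, `converged`, `n_iter`, and the `G` used.
#' @export
fit_st_gblup <- function(pheno, G, tol = 1e-8, par_tol = 1e-6,
                         max_iter = 500L) {
  check_columns(pheno, c("hybrid_id", "replicate", "value"), "phenotype table")
  hybrids <- rownames(G)
  if (is.null(hybrids)) stop("G must carry hybrid ids", call. = FALSE)
  if (!all(pheno$hybrid_id %in% hybrids))
    stop("phenotypes contain hybrids absent from G", call. = FALSE)
  pheno <- pheno[stats::complete.cases(pheno[, c("hybrid_id", "replicate",
                                                 "value")]), ]
  obs <- intersect(hybrids, unique(pheno$hybrid_id))
  if (length(obs) < 2 || nrow(pheno) < 4)
    stop("need at least 2 hybrids and 4 records", call. = FALSE)
  reps <- sort(unique(pheno$replicate))
  tab <- table(factor(pheno$hybrid_id, levels = obs),
               factor(pheno$replicate, levels = reps))
  balanced <- length(reps) >= 2 && all(tab == 1)
  v_y <- stats::var(pheno$value)

  if (balanced) {
    Gs <- G[obs, obs, drop = FALSE]
    Y <- matrix(NA_real_, length(obs), length(reps),
                dimnames = list(obs, reps))
    Y[cbind(match(pheno$hybrid_id, obs), match(pheno$replicate, reps))] <-
      pheno$value
    fit <- balanced_em_reml(Y, Gs, Phi = matrix(1, 1, 1), model = "st",
                            Sigma_a = matrix(v_y / 2, 1, 1),
                            R_par = list(sigma_e2 = v_y / 2),
                            tol = tol, par_tol = par_tol,
                            max_iter = max_iter)
    sigma_a2 <- fit$Sigma_a[1, 1]
    sigma_e2 <- fit$R_par$sigma_e2
    a_hat <- drop(fit$a_hat)
    names(a_hat) <- obs
    b_hat <- fit$mu_hat
    names(b_hat) <- reps
    method <- "em_eigen"
  } else {
    recs <- data.frame(plot_id = paste(pheno$hybrid_id, pheno$replicate,
                                       seq_len(nrow(pheno))),
                       hybrid_id = pheno$hybrid_id,
                       replicate = pheno$replicate, trait = 1L,
                       value = pheno$value, stringsAsFactors = FALSE)
    Gs <- G[obs, obs, drop = FALSE]
    fit <- general_em_reml(recs, Gs, n_traits = 1L,
                           Sigma_g = matrix(v_y / 2, 1, 1),
                           Sigma_e = matrix(v_y / 2, 1, 1),
                           tol = tol, par_tol = par_tol,
                           max_iter = max_iter)
    sigma_a2 <- fit$Sigma_g[1, 1]
    sigma_e2 <- fit$Sigma_e[1, 1]
    a_hat <- drop(fit$a_hat[, 1])
    names(a_hat) <- obs
    b_hat <- fit$b_hat
    method <- "em_mme"
  }
  structure(list(sigma_a2 = sigma_a2, sigma_e2 = sigma_e2,
                 h2 = heritability(sigma_a2, sigma_e2),
                 a_hat = a_hat, b_hat = b_hat, loglik = fit$loglik,
                 loglik_trace = fit$loglik_trace, converged = fit$converged,
                 n_iter = fit$n_iter, method = method, G = G,
                 obs_hybrids = obs),
            class = "st_gblup")
}

#' Narrow-sense heritability from variance components
#'
#' The ratio of the additive genetic variance to the sum of additive and
#' residual variance.
#'
#' @param sigma_a2 additive genetic variance (>= 0).
#' @param sigma_e2 residual variance (> 0, unless `sigma_a2 > 0`).
#' @return `sigma_a2 / (sigma_a2 + sigma_e2)`.
#' @examples
#' heritability(607.70, 792.10)  # 0.434
#' @export
heritability <- function(sigma_a2, sigma_e2) {
  if (any(sigma_a2 < 0) || any(sigma_e2 < 0))
    stop("variance components must be non-negative", call. = FALSE)
  tot <- sigma_a2 + sigma_e2
  if (any(tot <= 0))
    stop("heritability undefined when both variances are zero", call. = FALSE)
  sigma_a2 / tot
}

#' Solve Henderson's mixed-model equations at fixed variance components
#'
#' Direct dense solve of
#' `[X'X, X'Z; Z'X, Z'Z + (sigma_e2/sigma_a2) G^-1] [b; a] = [X'y; Z'y]`.
#' Useful for verifying BLUP solutions against a generalized-least-squares
#' computation and for small worked examples.
#'
#' @param y response vector.
#' @param X fixed-effect design matrix.
#' @param Z random-effect incidence matrix (columns match `G`).
#' @param G relationship matrix.
#' @param sigma_a2,sigma_e2 fixed variance components.
#' @return List with `b_hat` and `a_hat`.
#' @export
mme_solve <- function(y, X, Z, G, sigma_a2, sigma_e2) {
  stopifnot(length(y) == nrow(X), nrow(X) == nrow(Z),
            ncol(Z) == nrow(G), sigma_a2 > 0, sigma_e2 > 0)
  k <- sigma_e2 / sigma_a2
  Ginv <- chol2inv(chol(G))
  C <- rbind(cbind(crossprod(X), crossprod(X, Z)),
             cbind(crossprod(Z, X), crossprod(Z) + k * Ginv))
  rhs <- c(crossprod(X, y), crossprod(Z, y))
  sol <- solve(C, rhs)
  list(b_hat = sol[seq_len(ncol(X))],
       a_hat = sol[ncol(X) + seq_len(ncol(Z))])
}

#' Predict genetic values for hybrids, including unphenotyped ones
#'
#' Phenotyped hybrids return their BLUP from the fit. Hybrids present in the
#' relationship matrix but without records are predicted through their
#' genomic relationships with the phenotyped set,
#' `a_u = G_uo G_oo^-1 a_o`, which equals the full mixed-model-equation
#' solution for record-free individuals.
#'
#' @param fit an `st_gblup` or `mt_gblup` fit.
#' @param new_hybrid_ids hybrid ids to predict (must be rows of the fit's
#'   `G`).
#' @return data.frame with `hybrid_id` and predicted genetic value(s).
#' @export
predict_genetic_values <- function(fit, new_hybrid_ids) {
  G <- fit$G
  if (!all(new_hybrid_ids %in% rownames(G)))
    stop("hybrid id(s) absent from G: ",
         paste(setdiff(new_hybrid_ids, rownames(G)), collapse = ", "),
         call. = FALSE)
  A <- if (inherits(fit, "mt_gblup")) fit$a_hat else
    matrix(fit$a_hat, ncol = 1, dimnames = list(names(fit$a_hat), "gv"))
  obs <- rownames(A)
  unobs <- setdiff(new_hybrid_ids, obs)
  if (length(unobs)) {
    Goo <- G[obs, obs, drop = FALSE]
    Guo <- G[unobs, obs, drop = FALSE]
    A_u <- Guo %*% solve(Goo, A)
    A <- rbind(A, A_u)
  }
  out <- data.frame(hybrid_id = new_hybrid_ids, stringsAsFactors = FALSE)
  vals <- A[new_hybrid_ids, , drop = FALSE]
  if (ncol(vals) == 1) out$gv <- drop(vals)
  else for (j in seq_len(ncol(vals)))
    out[[paste0("gv_trait", j)]] <- vals[, j]
  out
}
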