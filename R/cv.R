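# Fivefold hybrid-level cross-validation: single-trait versus multi-trait
# genomic prediction with a vegetation index as secondary trait.

#' Assign hybrids to cross-validation folds
#'
#' Random partition at the hybrid level (all plots of a hybrid are masked
#' together); fold sizes differ by at most one.
#'
#' @param hybrid_ids vector of hybrid ids.
#' @param k number of folds (default 5).
#' @param seed integer seed (reproducible assignment).
#' @return data.frame with columns `hybrid_id`, `fold`; attribute `seed`.
#' @export
make_folds <- function(hybrid_ids, k = 5L, seed = 1L) {
  if (k < 2) stop("k must be at least 2", call. = FALSE)
  if (length(hybrid_ids) < k)
    stop("need at least k hybrids", call. = FALSE)
  out <- with_seed(seed, {
    shuffled <- sample(hybrid_ids)
    data.frame(hybrid_id = shuffled,
               fold = rep_len(seq_len(k), length(shuffled)),
               stringsAsFactors = FALSE)
  })
  out <- out[order(match(out$hybrid_id, hybrid_ids)), ]
  rownames(out) <- NULL
  attr(out, "seed") <- seed
  out
}

cv_fold_accuracy <- function(masked_pheno, value_col, pred) {
  y <- masked_pheno[[value_col]]
  p <- pred[masked_pheno$hybrid_id]
  if (stats::sd(y) < .Machine$double.eps ||
      stats::sd(p) < .Machine$double.eps) return(NA_real_)
  stats::cor(y, p)
}

#' Single-trait GBLUP cross-validation
#'
#' For each fold the trait records of the fold's hybrids are deleted (the
#' hybrids stay in `G`), a single-trait GBLUP is refitted on the remaining
#' plots (variance components re-estimated within the training set), and
#' genetic values of the masked hybrids are predicted through their genomic
#' relationships. Accuracy is the Pearson correlation between the masked
#' plots' raw phenotypic values and the predicted genetic value of their
#' hybrid. Folds whose masked plots have zero phenotypic variance are
#' flagged and excluded from the mean with a warning.
#'
#' @param pheno data.frame with `plot_id`, `hybrid_id`, `replicate` and the
#'   trait column.
#' @param trait name of the trait column.
#' @param folds fold assignment from [make_folds()].
#' @param G relationship matrix over all hybrids.
#' @param tol,max_iter convergence controls passed to [fit_st_gblup()].
#' @return List of class `cv_result`: `model`, `accuracy` (per fold),
#'   `mean_accuracy`, `masked_n`, `folds_used`.
#' @export
run_st_cv <- function(pheno, trait, folds, G, tol = 1e-8, max_iter = 500L) {
  check_columns(pheno, c("plot_id", "hybrid_id", "replicate", trait),
                "phenotype table")
  k <- max(folds$fold)
  acc <- numeric(k)
  masked_n <- integer(k)
  for (f in seq_len(k)) {
    masked <- folds$hybrid_id[folds$fold == f]
    train <- pheno[!pheno$hybrid_id %in% masked, ]
    test <- pheno[pheno$hybrid_id %in% masked, ]
    fit <- fit_st_gblup(data.frame(hybrid_id = train$hybrid_id,
                                   replicate = train$replicate,
                                   value = train[[trait]],
                                   stringsAsFactors = FALSE),
                        G, tol = tol, max_iter = max_iter)
    pred <- predict_genetic_values(fit, masked)
    pv <- pred$gv
    names(pv) <- pred$hybrid_id
    acc[f] <- cv_fold_accuracy(test, trait, pv)
    masked_n[f] <- length(masked)
  }
  if (anyNA(acc))
    warning("fold(s) with zero phenotypic or predictive variance excluded from the mean")
  structure(list(model = paste0("ST:", trait), accuracy = acc,
                 mean_accuracy = mean(acc, na.rm = TRUE),
                 masked_n = masked_n,
                 folds_used = sum(!is.na(acc))),
            class = "cv_result")
}

#' Multi-trait GBLUP cross-validation with a secondary trait
#'
#' Same folds as [run_st_cv()] (pass the identical assignment): per fold the
#' target-trait records of masked hybrids are deleted while the secondary
#' trait (typically a VI at one time point) stays observed for all hybrids.
#' A bivariate GBLUP is refitted on each training set and accuracy is
#' computed exactly as in the single-trait case.
#'
#' @param pheno data.frame with `plot_id`, `hybrid_id`, `replicate` and the
#'   target trait column.
#' @param trait name of the target trait column.
#' @param secondary data.frame with `plot_id`, `hybrid_id`, `replicate` and
#'   the secondary-trait column (same plots as `pheno`).
#' @param secondary_trait name of the secondary-trait column.
#' @param folds fold assignment from [make_folds()].
#' @param G relationship matrix over all hybrids.
#' @param tol,max_iter convergence controls.
#' @param start optional warm-start covariances passed to [fit_mt_gblup()].
#' @return List of class `cv_result` with the model label carrying the
#'   secondary trait.
#' @export
run_mt_cv <- function(pheno, trait, secondary, secondary_trait, folds, G,
                      tol = 1e-8, max_iter = 500L, start = NULL) {
  check_columns(pheno, c("plot_id", "hybrid_id", "replicate", trait),
                "phenotype table")
  check_columns(secondary, c("plot_id", "hybrid_id", "replicate",
                             secondary_trait), "secondary-trait table")
  mm <- match(pheno$plot_id, secondary$plot_id)
  if (anyNA(mm))
    stop("secondary trait missing for some plots", call. = FALSE)
  if (mean(is.na(secondary[[secondary_trait]][mm])) > 0.5)
    stop("secondary trait missing for more than half the plots",
         call. = FALSE)
  wide <- data.frame(plot_id = pheno$plot_id, hybrid_id = pheno$hybrid_id,
                     replicate = pheno$replicate,
                     target = pheno[[trait]],
                     secondary = secondary[[secondary_trait]][mm],
                     stringsAsFactors = FALSE)
  k <- max(folds$fold)
  acc <- numeric(k)
  masked_n <- integer(k)
  for (f in seq_len(k)) {
    masked <- folds$hybrid_id[folds$fold == f]
    dat <- wide
    dat$target[dat$hybrid_id %in% masked] <- NA
    fit <- fit_mt_gblup(dat, c("target", "secondary"), G, tol = tol,
                        max_iter = max_iter, start = start)
    pred <- fit$a_hat[masked, "target"]
    test <- pheno[pheno$hybrid_id %in% masked, ]
    acc[f] <- cv_fold_accuracy(test, trait, pred)
    masked_n[f] <- length(masked)
  }
  if (anyNA(acc))
    warning("fold(s) with zero phenotypic or predictive variance excluded from the mean")
  structure(list(model = paste0("MT:", trait, "+", secondary_trait),
                 accuracy = acc,
                 mean_accuracy = mean(acc, na.rm = TRUE),
                 masked_n = masked_n, folds_used = sum(!is.na(acc))),
            class = "cv_result")
}
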