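# Internal helpers shared across modules.

#' Derive a reproducible substream seed from a master seed
#'
#' All stochastic generators in the package draw their randomness from a
#' single master seed split into named substreams, so that any stage can be
#' regenerated in isolation without disturbing the others.
#'
#' @param master integer master seed.
#' @param name character substream label.
#' @return An integer seed below 2^31.
#' @keywords internal
substream_seed <- function(master, name) {
  # small deterministic hash of the label folded into the master seed
  codes <- utf8ToInt(name)
  h <- 0
  for (k in codes) h <- (h * 31 + k) %% 1000003L
  as.integer((abs(as.numeric(master)) * 7919 + h) %% 2147483629)
}

# Evaluate `expr` under `seed`, restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  expr
}

# Symmetric check with exact tolerance 0 used for GRMs built in-package.
is_symmetric_exact <- function(x) {
  is.matrix(x) && nrow(x) == ncol(x) && max(abs(x - t(x))) == 0
}

#' Bend a symmetric matrix to (near) positive definiteness
#'
#' Eigenvalues below `floor_frac * trace` are floored and the matrix is
#' reconstructed. Used for interim covariance estimates in the REML
#' iterations and for relationship-matrix regularization.
#'
#' @param x symmetric matrix.
#' @param floor_frac fraction of the trace used as the eigenvalue floor.
#' @return List with the bent `matrix` and logical `bent`.
#' @keywords internal
bend_psd <- function(x, floor_frac = 1e-6) {
  x <- (x + t(x)) / 2
  ee <- eigen(x, symmetric = TRUE)
  fl <- floor_frac * max(sum(abs(diag(x))), .Machine$double.eps)
  if (all(ee$values >= fl)) return(list(matrix = x, bent = FALSE))
  vals <- pmax(ee$values, fl)
  list(matrix = ee$vectors %*% (vals * t(ee$vectors)), bent = TRUE)
}

# Matrix square root via eigendecomposition; negative eigenvalues floored at 0.
mat_sqrt <- function(x) {
  ee <- eigen((x + t(x)) / 2, symmetric = TRUE)
  ee$vectors %*% (sqrt(pmax(ee$values, 0)) * t(ee$vectors))
}

# Stop with a consistent message when required columns are absent.
check_columns <- function(df, cols, what = "input table") {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0)
    stop(sprintf("%s is missing required column(s): %s", what,
                 paste(miss, collapse = ", ")), call. = FALSE)
  invisible(TRUE)
}
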