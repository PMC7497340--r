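# Marker QC, mode imputation, VanRaden GRM and hybrid relationships.

#' Marker quality control for a parental genotype panel
#'
#' Markers are removed when they exceed the missingness threshold, fall below
#' the minor-allele-frequency threshold, or exceed the heterozygosity
#' threshold. MAF and heterozygosity are computed over non-missing calls.
#' Filters are applied in that order and each removed marker is attributed to
#' the first filter it fails.
#'
#' @param g genotype matrix, individuals x markers, calls in {0, 1, 2, NA}.
#' @param max_missing maximum tolerated fraction of missing calls (0.15).
#' @param min_maf minimum minor allele frequency (0.01).
#' @param max_het maximum heterozygote fraction (0.01).
#' @return List with the filtered `genotypes` and a `report` containing
#'   per-filter counts and marker lists.
#' @export
qc_markers <- function(g, max_missing = 0.15, min_maf = 0.01,
                       max_het = 0.01) {
  g <- as.matrix(g)
  if (nrow(g) == 0 || ncol(g) == 0)
    stop("empty genotype matrix", call. = FALSE)
  check_geno_calls(g)
  if (is.null(colnames(g))) colnames(g) <- paste0("m", seq_len(ncol(g)))
  n_miss <- colMeans(is.na(g))
  p <- colMeans(g, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  het <- apply(g, 2, function(col) mean(col[!is.na(col)] == 1))
  fail_miss <- n_miss > max_missing
  fail_maf <- !fail_miss & (is.na(maf) | maf < min_maf)
  fail_het <- !fail_miss & !fail_maf & !is.na(het) & het > max_het
  keep <- !(fail_miss | fail_maf | fail_het)
  if (!any(keep))
    stop("all markers removed by QC; panel is empty", call. = FALSE)
  report <- list(
    n_input_markers = ncol(g),
    n_removed_missing = sum(fail_miss),
    n_removed_maf = sum(fail_maf),
    n_removed_het = sum(fail_het),
    n_retained = sum(keep),
    removed_missing = colnames(g)[fail_miss],
    removed_maf = colnames(g)[fail_maf],
    removed_het = colnames(g)[fail_het])
  list(genotypes = g[, keep, drop = FALSE], report = report)
}

check_geno_calls <- function(g) {
  vals <- g[!is.na(g)]
  if (length(vals) && !all(vals %in% c(0, 1, 2)))
    stop("genotype calls must be 0, 1, 2 or NA", call. = FALSE)
  invisible(TRUE)
}

#' Impute missing genotype calls with the marker mode
#'
#' Missing calls are replaced by the most frequent call at that marker; ties
#' are broken toward the lower genotype code so imputation is deterministic.
#' Non-missing calls are never altered.
#'
#' @param g genotype matrix, individuals x markers, calls in {0, 1, 2, NA}.
#' @return The matrix with no missing calls.
#' @export
impute_mode <- function(g) {
  g <- as.matrix(g)
  check_geno_calls(g)
  for (j in seq_len(ncol(g))) {
    miss <- is.na(g[, j])
    if (!any(miss)) next
    obs <- g[!miss, j]
    if (length(obs) == 0)
      stop(sprintf("marker %s is fully missing; remove it in QC first",
                   colnames(g)[j] %||% j), call. = FALSE)
    counts <- table(factor(obs, levels = c(0, 1, 2)))
    g[miss, j] <- as.numeric(names(counts)[which.max(counts)])
  }
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' VanRaden additive genomic relationship matrix
#'
#' Method-1 VanRaden GRM: `G = W W' / (2 * sum p_j (1 - p_j))` with W the
#' call matrix centered by twice the within-panel allele frequency `p_j`.
#' A small epsilon is added to the diagonal so downstream mixed-model
#' equations are invertible.
#'
#' @param g imputed, QC-passed genotype matrix (individuals x markers, no NA).
#' @param epsilon diagonal regularization constant.
#' @return Symmetric relationship matrix with the individuals' dimnames and
#'   attribute `epsilon`.
#' @export
vanraden_grm <- function(g, epsilon = 1e-6) {
  g <- as.matrix(g)
  if (nrow(g) < 2)
    stop("need at least two individuals", call. = FALSE)
  if (anyNA(g))
    stop("genotype matrix contains missing calls; impute first", call. = FALSE)
  check_geno_calls(g)
  p <- colMeans(g) / 2
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0)
    stop("all markers monomorphic; VanRaden denominator is zero",
         call. = FALSE)
  W <- sweep(g, 2, 2 * p)
  G <- tcrossprod(W) / denom
  G <- (G + t(G)) / 2
  diag(G) <- diag(G) + epsilon
  ids <- rownames(g) %||% paste0("ind", seq_len(nrow(g)))
  dimnames(G) <- list(ids, ids)
  attr(G, "epsilon") <- epsilon
  G
}

#' Hybrid genomic relationships from parental panels
#'
#' Assuming maternal and paternal panels are unrelated, the relationship
#' between hybrids i and j is `0.5 * (r(m_i, m_j) + r(p_i, p_j))`, including
#' the diagonal (i = j uses the parental self-relationships). The result is
#' regularized to positive definiteness with a diagonal epsilon.
#'
#' @param maternal_grm,paternal_grm parental relationship matrices with id
#'   dimnames (from [vanraden_grm()]).
#' @param pedigree data.frame with columns `hybrid_id`, `mother_id`,
#'   `father_id`.
#' @param epsilon diagonal regularization constant.
#' @return Hybrid relationship matrix (hybrids in pedigree order).
#' @export
hybrid_grm <- function(maternal_grm, paternal_grm, pedigree, epsilon = 1e-6) {
  check_columns(pedigree, c("hybrid_id", "mother_id", "father_id"), "pedigree")
  mi <- match(pedigree$mother_id, rownames(maternal_grm))
  pi_ <- match(pedigree$father_id, rownames(paternal_grm))
  if (anyNA(mi))
    stop("pedigree error: unknown mother id(s): ",
         paste(unique(pedigree$mother_id[is.na(mi)]), collapse = ", "),
         call. = FALSE)
  if (anyNA(pi_))
    stop("pedigree error: unknown father id(s): ",
         paste(unique(pedigree$father_id[is.na(pi_)]), collapse = ", "),
         call. = FALSE)
  H <- 0.5 * (maternal_grm[mi, mi, drop = FALSE] +
              paternal_grm[pi_, pi_, drop = FALSE])
  H <- (H + t(H)) / 2
  diag(H) <- diag(H) + epsilon
  # bump the shift if tiny negative eigenvalues survive
  ev_min <- min(eigen(H, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min <= 0) diag(H) <- diag(H) + (abs(ev_min) + epsilon)
  dimnames(H) <- list(pedigree$hybrid_id, pedigree$hybrid_id)
  attr(H, "epsilon") <- epsilon
  H
}
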