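# Synthetic longitudinal VI phenotypes and end-of-season traits.

#' Simulation configuration for a single site-year trial
#'
#' Bundles the true parameters of the generative model: spline-coefficient
#' genetic covariance `Sigma_a_true` (structured across hybrids by the
#' relationship matrix), permanent-environment covariance `Sigma_pe_true`
#' (independent across plots), per-flight residual variances, and the
#' heritability / genetic-correlation targets for the end-of-season traits.
#' Defaults emulate a maize hybrid trial: five flights on the thermal-time
#' axis of a typical season (GDD 524 to 1501), three knots at the first,
#' middle and last flight, NDVI-scale variances giving per-flight
#' heritabilities around 0.3-0.55, a yield-like trait (h2 0.4) and a
#' moisture-like trait (h2 0.85), each genetically correlated 0.8 with the
#' mid-season VI genetic value.
#'
#' @param n_maternal,n_paternal,n_markers,n_hybrids genotype-panel and
#'   crossing-design dimensions.
#' @param n_reps replicate blocks in the RCBD (default 2).
#' @param flight_gdds cumulative GDD of each flight.
#' @param knot_gdds knot GDDs; must be a subset of `flight_gdds` with the
#'   first and last flight included.
#' @param Sigma_a_true m x m genetic covariance of spline coefficients.
#' @param Sigma_pe_true m x m permanent-environment covariance.
#' @param resid_vars_true per-flight residual variances (> 0).
#' @param eos_h2 named heritabilities of the end-of-season traits.
#' @param r_g_eos genetic correlation between each end-of-season trait and
#'   the VI genetic value at `eos_time_point`.
#' @param eos_time_point flight index anchoring the genetic correlation.
#' @param seed master seed; substreams are derived per generator.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_maternal = 40, n_paternal = 40, n_markers = 1000,
                       n_hybrids = 300, n_reps = 2,
                       flight_gdds = c(524, 816, 1129, 1173, 1501),
                       knot_gdds = c(524, 1129, 1501),
                       Sigma_a_true = NULL, Sigma_pe_true = NULL,
                       resid_vars_true = NULL,
                       eos_h2 = c(yield = 0.4, moisture = 0.85),
                       r_g_eos = 0.8, eos_time_point = 3, seed = 1) {
  m <- length(knot_gdds)
  if (is.null(Sigma_a_true)) {
    sds <- c(0.04, 0.05, 0.05)[seq_len(min(3, m))]
    if (m > 3) sds <- c(sds, rep(0.05, m - 3))
    R <- matrix(0.7, m, m) + diag(m) * 0.3
    if (m >= 3) { R[1, m] <- R[m, 1] <- 0.5 }
    Sigma_a_true <- diag(sds) %*% R %*% diag(sds)
  }
  if (is.null(Sigma_pe_true))
    Sigma_pe_true <- 0.0009 * (matrix(0.5, m, m) + diag(m) * 0.5)
  if (is.null(resid_vars_true))
    resid_vars_true <- rep(c(0.0016, 0.0012, 0.0009),
                           length.out = length(flight_gdds))
  cfg <- list(n_maternal = n_maternal, n_paternal = n_paternal,
              n_markers = n_markers, n_hybrids = n_hybrids, n_reps = n_reps,
              flight_gdds = flight_gdds, knot_gdds = knot_gdds,
              Sigma_a_true = as.matrix(Sigma_a_true),
              Sigma_pe_true = as.matrix(Sigma_pe_true),
              resid_vars_true = resid_vars_true, eos_h2 = eos_h2,
              r_g_eos = r_g_eos, eos_time_point = eos_time_point, seed = seed)
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  m <- length(cfg$knot_gdds)
  if (!all(cfg$knot_gdds %in% cfg$flight_gdds))
    stop("knot_gdds must be a subset of flight_gdds", call. = FALSE)
  if (is.unsorted(cfg$knot_gdds, strictly = TRUE) ||
      is.unsorted(cfg$flight_gdds, strictly = TRUE))
    stop("flight_gdds and knot_gdds must be strictly increasing",
         call. = FALSE)
  if (cfg$knot_gdds[1] != cfg$flight_gdds[1] ||
      cfg$knot_gdds[m] != utils::tail(cfg$flight_gdds, 1))
    stop("first and last knot must flank all flights", call. = FALSE)
  for (nm in c("Sigma_a_true", "Sigma_pe_true")) {
    S <- cfg[[nm]]
    if (nrow(S) != m || ncol(S) != m)
      stop(sprintf("%s must be %d x %d", nm, m, m), call. = FALSE)
    if (max(abs(S - t(S))) > 1e-10)
      stop(sprintf("%s must be symmetric", nm), call. = FALSE)
    if (min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
      stop(sprintf("%s must be positive semidefinite", nm), call. = FALSE)
  }
  if (length(cfg$resid_vars_true) != length(cfg$flight_gdds) ||
      any(cfg$resid_vars_true <= 0))
    stop("resid_vars_true must be positive, one per flight", call. = FALSE)
  if (any(abs(cfg$r_g_eos) > 1))
    stop("|r_g_eos| must be <= 1", call. = FALSE)
  if (any(cfg$eos_h2 < 0 | cfg$eos_h2 > 1))
    stop("eos_h2 must lie in [0, 1]", call. = FALSE)
  if (cfg$eos_time_point < 1 ||
      cfg$eos_time_point > length(cfg$flight_gdds))
    stop("eos_time_point out of range", call. = FALSE)
  invisible(cfg)
}

# Saturating logistic mean curve in (0.2, 0.95), mimicking how canopy VIs
# rise and then saturate over thermal time.
vi_mean_curve <- function(gdd) {
  0.2 + 0.72 / (1 + exp(-(gdd - 650) / 180))
}

#' Simulate longitudinal vegetation-index trajectories
#'
#' Hybrid-level spline coefficient vectors are drawn with covariance
#' `Sigma_a_true (x) G` (Kronecker across hybrids), one
#' permanent-environment coefficient vector per plot with covariance
#' `Sigma_pe_true`, and the observation at flight t is
#' `mean_curve(gdd_t) + z(t)'a + z(t)'pe + e` with time-specific residual
#' variance. Genetic values are structured by a matrix square root of `G`
#' (negative eigenvalues floored at zero).
#'
#' @param config a [sim_config()] object.
#' @param layout field layout from [make_field_layout()]; hybrids must match
#'   the rows of `grm`.
#' @param grm relationship matrix over the hybrids in `layout`.
#' @return List with `phenotypes` (long data.frame: plot_id, hybrid_id,
#'   replicate, time_label, gdd, value), `true_coeffs` (hybrids x knots),
#'   `true_pe` (plots x knots) and the knot vector.
#' @export
simulate_vi_trajectories <- function(config, layout, grm) {
  stopifnot(inherits(config, "sim_config"))
  hybrids <- rownames(grm)
  if (is.null(hybrids)) stop("grm must carry hybrid ids", call. = FALSE)
  if (!all(layout$hybrid_id %in% hybrids))
    stop("layout contains hybrids absent from the relationship matrix",
         call. = FALSE)
  q <- nrow(grm)
  m <- length(config$knot_gdds)
  Z <- spline_basis(config$flight_gdds, config$knot_gdds)
  A <- with_seed(substream_seed(config$seed, "vi_genetic"), {
    mat_sqrt(grm) %*% matrix(stats::rnorm(q * m), q, m) %*%
      t(mat_sqrt(config$Sigma_a_true))
  })
  rownames(A) <- hybrids
  P <- nrow(layout)
  PE <- with_seed(substream_seed(config$seed, "vi_pe"), {
    matrix(stats::rnorm(P * m), P, m) %*% t(mat_sqrt(config$Sigma_pe_true))
  })
  rownames(PE) <- layout$plot_id
  n_t <- length(config$flight_gdds)
  E <- with_seed(substream_seed(config$seed, "vi_resid"), {
    matrix(stats::rnorm(P * n_t, 0,
                        rep(sqrt(config$resid_vars_true), each = P)), P, n_t)
  })
  mu <- vi_mean_curve(config$flight_gdds)
  vals <- matrix(rep(mu, each = P), P, n_t) +
    A[layout$hybrid_id, , drop = FALSE] %*% t(Z) + PE %*% t(Z) + E
  pheno <- data.frame(
    plot_id = rep(layout$plot_id, n_t),
    hybrid_id = rep(layout$hybrid_id, n_t),
    replicate = rep(layout$replicate, n_t),
    time_label = rep(paste0("t", seq_len(n_t)), each = P),
    gdd = rep(config$flight_gdds, each = P),
    value = as.vector(vals), stringsAsFactors = FALSE)
  list(phenotypes = pheno, true_coeffs = A, true_pe = PE,
       knots = config$knot_gdds)
}

#' Simulate end-of-season traits genetically correlated with a VI
#'
#' Each trait's genetic value is built as
#' `r_g * std(VI genetic value at the anchor flight) +
#'  sqrt(1 - r_g^2) * independent G-structured deviate`,
#' scaled so the trait heritability equals `eos_h2`, then plot residuals are
#' added. Yield-like and moisture-like scales follow typical maize trial
#' magnitudes (mean 180 bu/ac, total variance 1000; mean 20 pct, total
#' variance 5).
#'
#' @param config a [sim_config()] object.
#' @param true_coeffs hybrid x knot coefficient matrix from
#'   [simulate_vi_trajectories()].
#' @param grm relationship matrix over the hybrids.
#' @param layout field layout.
#' @param seed integer seed (defaults to a substream of the config seed).
#' @return List with `phenotypes` (plot_id, hybrid_id, replicate, one column
#'   per trait) and `true_genetic` (hybrid x trait matrix of genetic values).
#' @export
simulate_end_of_season <- function(config, true_coeffs, grm, layout,
                                   seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (any(abs(config$r_g_eos) > 1))
    stop("|r_g_eos| must be <= 1", call. = FALSE)
  if (is.null(seed)) seed <- substream_seed(config$seed, "eos")
  hybrids <- rownames(grm)
  q <- length(hybrids)
  z_anchor <- spline_covariables(config$flight_gdds[config$eos_time_point],
                                 config$knot_gdds)
  gv_vi <- drop(true_coeffs %*% z_anchor)
  std <- function(x) {
    s <- stats::sd(x)
    if (s < .Machine$double.eps) rep(0, length(x)) else (x - mean(x)) / s
  }
  scales <- list(yield = c(mean = 180, total_var = 1000),
                 moisture = c(mean = 20, total_var = 5))
  traits <- names(config$eos_h2)
  r_g <- rep(config$r_g_eos, length.out = length(traits))
  Gh <- mat_sqrt(grm)
  out <- layout[, c("plot_id", "hybrid_id", "replicate")]
  truth <- matrix(0, q, length(traits), dimnames = list(hybrids, traits))
  with_seed(seed, {
    for (k in seq_along(traits)) {
      tr <- traits[k]
      sc <- scales[[tr]] %||% c(mean = 0, total_var = 1)
      u <- std(drop(Gh %*% stats::rnorm(q)))
      g_std <- r_g[k] * std(gv_vi) + sqrt(1 - r_g[k]^2) * u
      h2 <- config$eos_h2[[tr]]
      sigma_g2 <- h2 * sc[["total_var"]]
      sigma_e2 <- (1 - h2) * sc[["total_var"]]
      g <- g_std * sqrt(sigma_g2)
      truth[, k] <- g
      e <- if (sigma_e2 > 0) stats::rnorm(nrow(layout), 0, sqrt(sigma_e2))
           else rep(0, nrow(layout))
      out[[tr]] <- sc[["mean"]] + g[match(layout$hybrid_id, hybrids)] + e
    }
  })
  list(phenotypes = out, true_genetic = truth)
}

#' Simulate a single plot-level trait with known variance components
#'
#' Convenience generator for an RCBD trial: hybrid genetic values with
#' covariance `sigma_a2 * G` and i.i.d. plot residuals with variance
#' `sigma_e2`, plus a replicate effect.
#'
#' @param G relationship matrix with hybrid ids as dimnames.
#' @param n_reps replicate blocks.
#' @param sigma_a2,sigma_e2 additive and residual variances.
#' @param mean overall mean.
#' @param rep_effect_sd standard deviation of the replicate (block) effects.
#' @param seed integer seed.
#' @return List with `phenotypes` (plot_id, hybrid_id, replicate, value) and
#'   `true_genetic` (named vector).
#' @export
simulate_trait <- function(G, n_reps = 2, sigma_a2 = 500, sigma_e2 = 850,
                           mean = 180, rep_effect_sd = 5, seed = 1) {
  hybrids <- rownames(G) %||% paste0("H", seq_len(nrow(G)))
  q <- nrow(G)
  layout <- make_field_layout(hybrids, n_reps)
  with_seed(seed, {
    g <- sqrt(sigma_a2) * drop(mat_sqrt(G) %*% stats::rnorm(q))
    names(g) <- hybrids
    b <- stats::rnorm(n_reps, 0, rep_effect_sd)
    names(b) <- paste0("rep", seq_len(n_reps))
    e <- stats::rnorm(nrow(layout), 0, sqrt(sigma_e2))
    layout$value <- mean + b[layout$replicate] + g[layout$hybrid_id] + e
    list(phenotypes = layout[, c("plot_id", "hybrid_id", "replicate",
                                 "value")],
         true_genetic = g)
  })
}
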