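# Shared fixture builders; everything is generated in code at test time.

identity_grm <- function(q, prefix = "H") {
  G <- diag(q)
  rownames(G) <- colnames(G) <- paste0(prefix, seq_len(q))
  G
}

# Full synthetic trial: genotyped parents -> hybrids -> GRM -> longitudinal
# VI + end-of-season traits. Small marker panel keeps tests fast.
build_trial <- function(seed, q = 120, r_g = 0.8, h2_yield = 0.4,
                        n_parents = 25, n_markers = 300, ...) {
  mat <- simulate_parents(n_parents, n_markers, seed = seed * 10 + 1,
                          prefix = "M")
  pat <- simulate_parents(n_parents, n_markers, seed = seed * 10 + 2,
                          prefix = "F")
  ped <- simulate_hybrids(mat, pat, q, seed = seed * 10 + 3)
  H <- hybrid_grm(vanraden_grm(impute_mode(mat)),
                  vanraden_grm(impute_mode(pat)), ped)
  cfg <- sim_config(n_hybrids = q, r_g_eos = r_g,
                    eos_h2 = c(yield = h2_yield, moisture = 0.85),
                    seed = seed, ...)
  lay <- make_field_layout(ped$hybrid_id, cfg$n_reps)
  vi <- simulate_vi_trajectories(cfg, lay, H)
  eos <- simulate_end_of_season(cfg, vi$true_coeffs, H, lay)
  list(G = H, cfg = cfg, layout = lay, vi = vi, eos = eos, pedigree = ped)
}

# VI phenotypes at one flight, shaped for use as a secondary trait.
vi_at_flight <- function(trial, flight = 3) {
  out <- trial$vi$phenotypes[trial$vi$phenotypes$time_label ==
                               paste0("t", flight), ]
  names(out)[names(out) == "value"] <- "vi"
  out
}

# Independent dense GLS oracle for BLUP solutions at fixed components.
gls_oracle <- function(y, X, Z, G, sigma_a2, sigma_e2) {
  V <- sigma_a2 * Z %*% G %*% t(Z) + sigma_e2 * diag(length(y))
  Vi <- solve(V)
  b <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  a <- sigma_a2 * G %*% t(Z) %*% Vi %*% (y - X %*% b)
  list(b_hat = drop(b), a_hat = drop(a))
}
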