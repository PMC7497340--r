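test_that("parent simulation is reproducible and respects the inbred limit", {
  g1 <- simulate_parents(4, 10, maf_range = c(0.3, 0.5), seed = 1,
                         het_rate = 0)
  g2 <- simulate_parents(4, 10, maf_range = c(0.3, 0.5), seed = 1,
                         het_rate = 0)
  expect_identical(g1, g2)
  expect_true(all(g1 %in% c(0, 2)))
  g3 <- simulate_parents(4, 10, maf_range = c(0.3, 0.5), seed = 2,
                         het_rate = 0)
  expect_false(identical(unclass(g1), unclass(g3)))
  expect_error(simulate_parents(4, 10, maf_range = c(0, 0.6)), "maf_range")
})

test_that("realized allele frequencies track the sampling distribution", {
  n <- 200
  g <- simulate_parents(n, 2000, maf_range = c(0.05, 0.5), seed = 7,
                        het_rate = 0)
  p_true <- attr(g, "allele_freqs")
  p_hat <- colMeans(g) / 2
  # each marker is n binomial draws: |p_hat - p| within 5 binomial SEs
  se <- sqrt(p_true * (1 - p_true) / n)
  expect_true(all(abs(p_hat - p_true) <= 5 * se))
  expect_lt(mean(abs(p_hat - p_true)), 0.04)
})

test_that("hybrid crossing draws distinct pairs and errors past the factorial", {
  m <- simulate_parents(2, 5, seed = 1, prefix = "M")
  p <- simulate_parents(2, 5, seed = 2, prefix = "F")
  ped <- simulate_hybrids(m, p, 4, seed = 3)
  expect_equal(sort(paste(ped$mother_id, ped$father_id)),
               sort(paste(rep(c("M1", "M2"), 2), rep(c("F1", "F2"), each = 2))))
  expect_identical(ped, simulate_hybrids(m, p, 4, seed = 3))
  one <- simulate_hybrids(m[1, , drop = FALSE], p[1, , drop = FALSE], 1)
  expect_equal(one$mother_id, "M1")
  expect_equal(one$father_id, "F1")
  expect_error(simulate_hybrids(m, p, 5), "exceeds")
})

test_that("simulated weather is plausible and exercises both GDD caps", {
  w <- simulate_weather(as.Date("2016-05-10"), 150, seed = 4)
  expect_equal(nrow(w), 150)
  expect_true(all(w$tmin <= w$tmax))
  expect_gt(sum(w$tmax > 30), 0)
  expect_gt(sum(w$tmin < 10), 0)
  w60 <- simulate_weather(as.Date("2016-05-10"), 60, seed = 5)
  expect_gt(sum(w60$tmax > 30), 0)
  expect_identical(w, simulate_weather(as.Date("2016-05-10"), 150, seed = 4))
})

test_that("field layout is an RCBD: every hybrid once per replicate", {
  lay <- make_field_layout(paste0("H", 1:7), n_reps = 3)
  expect_equal(nrow(lay), 21)
  expect_true(all(table(lay$hybrid_id, lay$replicate) == 1))
  expect_false(anyDuplicated(lay$plot_id) > 0)
})

test_that("degenerate trajectory simulation collapses to the mean curve", {
  q <- 10
  G <- identity_grm(q)
  m <- 3
  cfg <- sim_config(n_hybrids = q,
                    Sigma_a_true = matrix(0, m, m),
                    Sigma_pe_true = matrix(0, m, m),
                    resid_vars_true = rep(1e-20, 5), seed = 2)
  lay <- make_field_layout(rownames(G), 2)
  sim <- simulate_vi_trajectories(cfg, lay, G)
  by_time <- split(sim$phenotypes$value, sim$phenotypes$gdd)
  for (v in by_time) expect_lt(diff(range(v)), 1e-8)
  expect_true(all(abs(sim$true_coeffs) < 1e-12))
})

test_that("two replicates of a hybrid differ only through pe and residual", {
  q <- 6
  G <- identity_grm(q)
  cfg <- sim_config(n_hybrids = q, Sigma_pe_true = matrix(0, 3, 3),
                    resid_vars_true = rep(1e-20, 5), seed = 3)
  lay <- make_field_layout(rownames(G), 2)
  sim <- simulate_vi_trajectories(cfg, lay, G)
  ph <- sim$phenotypes
  for (h in rownames(G)) {
    r1 <- ph$value[ph$hybrid_id == h & ph$replicate == "rep1"]
    r2 <- ph$value[ph$hybrid_id == h & ph$replicate == "rep2"]
    expect_equal(r1, r2, tolerance = 1e-7)
  }
})

test_that("simulated spline coefficients recover their covariance at scale", {
  q <- 500
  G <- identity_grm(q)
  cfg <- sim_config(n_hybrids = q, seed = 6)
  lay <- make_field_layout(rownames(G), 2)
  sim <- simulate_vi_trajectories(cfg, lay, G)
  S_emp <- crossprod(sim$true_coeffs) / q
  # Wishart-scale sampling error: SE(S_ij) ~ sqrt((S_ii S_jj + S_ij^2)/q)
  S <- cfg$Sigma_a_true
  for (i in 1:3) for (j in 1:3) {
    se <- sqrt((S[i, i] * S[j, j] + S[i, j]^2) / q)
    expect_lt(abs(S_emp[i, j] - S[i, j]), 4 * se)
  }
})

test_that("end-of-season traits hit their target heritability and correlation", {
  q <- 400
  G <- identity_grm(q)
  cfg <- sim_config(n_hybrids = q, eos_h2 = c(yield = 0.4, moisture = 0.85),
                    r_g_eos = 0.8, seed = 9)
  lay <- make_field_layout(rownames(G), 2)
  sim <- simulate_vi_trajectories(cfg, lay, G)
  eos <- simulate_end_of_season(cfg, sim$true_coeffs, G, lay)
  g <- eos$true_genetic[, "yield"]
  resid <- eos$phenotypes$yield - 180 -
    g[match(eos$phenotypes$hybrid_id, rownames(G))]
  h2_real <- var(g) / (var(g) + var(resid))
  expect_lt(abs(h2_real - 0.4), 0.03)
  # genetic correlation with the VI genetic value at the anchor flight
  z <- spline_covariables(cfg$flight_gdds[cfg$eos_time_point],
                          cfg$knot_gdds)
  gv_vi <- drop(sim$true_coeffs %*% z)
  expect_lt(abs(cor(gv_vi, g) - 0.8), 0.08)
})

test_that("a zero genetic correlation target yields near-zero realized correlation", {
  q <- 400
  G <- identity_grm(q)
  cfg <- sim_config(n_hybrids = q, r_g_eos = 0, seed = 10)
  lay <- make_field_layout(rownames(G), 2)
  sim <- simulate_vi_trajectories(cfg, lay, G)
  eos <- simulate_end_of_season(cfg, sim$true_coeffs, G, lay)
  z <- spline_covariables(cfg$flight_gdds[cfg$eos_time_point],
                          cfg$knot_gdds)
  gv_vi <- drop(sim$true_coeffs %*% z)
  expect_lt(abs(cor(gv_vi, eos$true_genetic[, "yield"])), 0.12)
})

test_that("perfect correlation and heritability give an affine relation", {
  q <- 50
  G <- identity_grm(q)
  cfg <- sim_config(n_hybrids = q, r_g_eos = 1,
                    eos_h2 = c(yield = 1, moisture = 1), seed = 11)
  lay <- make_field_layout(rownames(G), 2)
  sim <- simulate_vi_trajectories(cfg, lay, G)
  eos <- simulate_end_of_season(cfg, sim$true_coeffs, G, lay)
  z <- spline_covariables(cfg$flight_gdds[cfg$eos_time_point],
                          cfg$knot_gdds)
  gv_vi <- drop(sim$true_coeffs %*% z)
  y <- eos$phenotypes$yield[match(rownames(G), eos$phenotypes$hybrid_id)]
  expect_gt(abs(cor(gv_vi, y)), 1 - 1e-9)
})

test_that("invalid simulation configurations are rejected", {
  expect_error(sim_config(r_g_eos = 1.2), "r_g_eos")
  expect_error(sim_config(knot_gdds = c(816, 1129, 1501)), "flank")
  expect_error(sim_config(knot_gdds = c(524, 900, 1501)), "subset")
  expect_error(sim_config(resid_vars_true = rep(-1, 5)), "positive")
  expect_error(sim_config(Sigma_a_true = matrix(c(1, 2, 2, 1), 2)), "3 x 3")
})
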