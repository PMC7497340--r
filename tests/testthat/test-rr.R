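test_that("random regression recovers the genetic spline covariance", {
  q <- 200
  G <- identity_grm(q)
  devs <- vapply(301:303, function(s) {
    cfg <- sim_config(n_hybrids = q, seed = s)
    lay <- make_field_layout(rownames(G), 2)
    sim <- simulate_vi_trajectories(cfg, lay, G)
    fit <- fit_random_regression(sim$phenotypes, cfg$knot_gdds, G)
    expect_true(all(diff(fit$loglik_trace) >= -1e-10))
    max(abs(fit$Sigma_a - cfg$Sigma_a_true))
  }, numeric(1))
  # elementwise deviations stay within Monte-Carlo scale of the truth
  expect_lt(mean(devs), 0.0012)
})

test_that("estimated genetic effects at knots track the simulated truth", {
  q <- 200
  G <- identity_grm(q)
  cfg <- sim_config(n_hybrids = q, seed = 42)
  lay <- make_field_layout(rownames(G), 2)
  sim <- simulate_vi_trajectories(cfg, lay, G)
  fit <- fit_random_regression(sim$phenotypes, cfg$knot_gdds, G)
  for (k in seq_along(cfg$knot_gdds))
    expect_gt(cor(fit$a_hat[, k], sim$true_coeffs[, k]), 0.6)
})

test_that("a null permanent-environment component shrinks toward the boundary", {
  # The boundary-knot pe coefficient is weakly identified (it loads a
  # single flight), so its raw estimate carries amplified sampling noise;
  # the meaningful check is that null-pe fits are clearly separated from
  # fits under the true nonzero pe covariance.
  q <- 150
  G <- identity_grm(q)
  tr_null <- vapply(1:3, function(s) {
    cfg <- sim_config(n_hybrids = q,
                      Sigma_pe_true = matrix(0, 3, 3), seed = 200 + s)
    lay <- make_field_layout(rownames(G), 2)
    sim <- simulate_vi_trajectories(cfg, lay, G)
    fit <- fit_random_regression(sim$phenotypes, cfg$knot_gdds, G,
                                 max_iter = 1000)
    # interior-knot variance is well identified and must sit near zero
    expect_lt(fit$Sigma_pe[2, 2], 0.05 * diag(fit$Sigma_a)[2] + 1e-4)
    sum(diag(fit$Sigma_pe))
  }, numeric(1))
  tr_alt <- vapply(1:2, function(s) {
    cfg <- sim_config(n_hybrids = q, seed = 210 + s)  # default nonzero pe
    lay <- make_field_layout(rownames(G), 2)
    sim <- simulate_vi_trajectories(cfg, lay, G)
    fit <- fit_random_regression(sim$phenotypes, cfg$knot_gdds, G,
                                 max_iter = 1000)
    sum(diag(fit$Sigma_pe))
  }, numeric(1))
  expect_lt(mean(tr_null), 0.4 * mean(tr_alt))
})

test_that("identifiability and balance preconditions are enforced", {
  q <- 10
  G <- identity_grm(q)
  cfg <- sim_config(n_hybrids = q, seed = 1)
  lay <- make_field_layout(rownames(G), 2)
  sim <- simulate_vi_trajectories(cfg, lay, G)
  expect_error(fit_random_regression(sim$phenotypes,
                                     knots = c(524, 700, 816, 1000, 1129,
                                               1400, 1501), G),
               "identifiability")
  expect_error(fit_random_regression(sim$phenotypes[-1, ],
                                     cfg$knot_gdds, G), "balanced")
})

test_that("genetic curves interpolate the knot coefficients", {
  q <- 30
  G <- identity_grm(q)
  cfg <- sim_config(n_hybrids = q, seed = 3)
  lay <- make_field_layout(rownames(G), 2)
  sim <- simulate_vi_trajectories(cfg, lay, G)
  fit <- fit_random_regression(sim$phenotypes, cfg$knot_gdds, G)
  cur <- genetic_curves(fit, cfg$knot_gdds)
  for (k in seq_along(cfg$knot_gdds)) {
    at_k <- cur$genetic_value[cur$gdd == cfg$knot_gdds[k]]
    expect_equal(at_k, unname(fit$a_hat[, k]), tolerance = 1e-10)
  }
  # a group of one hybrid equals that hybrid's curve
  g1 <- genetic_curves(fit, c(600, 900), groups = list(solo = "H1"))
  ind <- genetic_curves(fit, c(600, 900))
  expect_equal(g1$genetic_value,
               ind$genetic_value[ind$hybrid == "H1"], tolerance = 1e-12)
  expect_error(genetic_curves(fit, 700, groups = list(bad = character(0))),
               "empty")
})

test_that("groups with separated coefficients give ordered curves everywhere", {
  q <- 40
  G <- identity_grm(q)
  cfg <- sim_config(n_hybrids = q, seed = 4)
  lay <- make_field_layout(rownames(G), 2)
  sim <- simulate_vi_trajectories(cfg, lay, G)
  fit <- fit_random_regression(sim$phenotypes, cfg$knot_gdds, G)
  # synthetic fit object with disjoint coefficient ranges
  fit$a_hat[1:20, ] <- abs(fit$a_hat[1:20, ]) + 0.05
  fit$a_hat[21:40, ] <- -abs(fit$a_hat[21:40, ]) - 0.05
  grid <- seq(524, 1501, length.out = 25)
  cur <- genetic_curves(fit, grid,
                        groups = list(high = rownames(G)[1:20],
                                      low = rownames(G)[21:40]))
  hi <- cur$genetic_value[cur$group == "high"]
  lo <- cur$genetic_value[cur$group == "low"]
  expect_true(all(hi > lo))
})
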