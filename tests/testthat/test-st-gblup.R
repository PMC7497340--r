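test_that("heritability is the stated variance ratio", {
  expect_equal(round(heritability(607.70, 792.10), 2), 0.43)
  expect_equal(round(heritability(4.89, 0.62), 2), 0.89)
  expect_equal(heritability(0, 5), 0)
  expect_error(heritability(0, 0), "undefined")
  expect_error(heritability(-1, 5), "non-negative")
})

test_that("MME solutions equal the dense GLS oracle on tiny instances", {
  set.seed(5)
  for (case in 1:6) {
    nh <- sample(2:4, 1)
    nrec <- sample(6:12, 1)
    G <- crossprod(matrix(rnorm(nh * nh), nh)) / nh + diag(nh)
    hyb <- c(seq_len(nh), sample(seq_len(nh), nrec - nh, replace = TRUE))
    rep_ <- c(1, 2, sample(1:2, nrec - 2, replace = TRUE))  # both blocks
    X <- cbind(1, as.numeric(rep_ == 2))
    Z <- matrix(0, nrec, nh)
    Z[cbind(seq_len(nrec), hyb)] <- 1
    y <- rnorm(nrec, 10)
    sa <- runif(1, 0.5, 3)
    se <- runif(1, 0.5, 3)
    mme <- mme_solve(y, X, Z, G, sa, se)
    ora <- gls_oracle(y, X, Z, G, sa, se)
    expect_equal(mme$a_hat, ora$a_hat, tolerance = 1e-8,
                 ignore_attr = TRUE)
    expect_equal(mme$b_hat, ora$b_hat, tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
})

test_that("the EM fit's BLUPs match the MME at its own estimates", {
  q <- 60
  G <- identity_grm(q)
  sim <- simulate_trait(G, sigma_a2 = 40, sigma_e2 = 60, seed = 2)
  fit <- fit_st_gblup(sim$phenotypes, G)
  ph <- sim$phenotypes
  X <- stats::model.matrix(~ 0 + factor(replicate), ph)
  Z <- stats::model.matrix(~ 0 + factor(hybrid_id, levels = rownames(G)), ph)
  mme <- mme_solve(ph$value, X, Z, G, fit$sigma_a2, fit$sigma_e2)
  expect_equal(unname(fit$a_hat), unname(mme$a_hat), tolerance = 1e-6)
})

test_that("restricted log-likelihood is monotone under EM", {
  q <- 80
  G <- identity_grm(q)
  sim <- simulate_trait(G, sigma_a2 = 500, sigma_e2 = 850, seed = 4)
  fit <- fit_st_gblup(sim$phenotypes, G)
  expect_true(all(diff(fit$loglik_trace) >= -1e-10))
  expect_true(fit$converged)
  expect_gte(fit$h2, 0)
  expect_lte(fit$h2, 1)
})

test_that("variance components are recovered across seeds", {
  q <- 150
  G <- identity_grm(q)
  h2_hat <- vapply(1:6, function(s) {
    sim <- simulate_trait(G, sigma_a2 = 500, sigma_e2 = 850, seed = s)
    fit_st_gblup(sim$phenotypes, G)$h2
  }, numeric(1))
  expect_lt(abs(mean(h2_hat) - 500 / 1350), 0.07)
  expect_true(all(h2_hat >= 0 & h2_hat <= 1))
})

test_that("a null trait drives the additive variance to the boundary", {
  q <- 150
  G <- identity_grm(q)
  frac <- vapply(1:6, function(s) {
    sim <- simulate_trait(G, sigma_a2 = 0, sigma_e2 = 850, seed = 100 + s)
    fit <- fit_st_gblup(sim$phenotypes, G)
    fit$sigma_a2 / (fit$sigma_a2 + fit$sigma_e2)
  }, numeric(1))
  expect_gte(mean(frac < 0.05), 0.5)
  expect_lt(mean(frac), 0.05)
})

test_that("balanced and MME engines agree on the same data", {
  q <- 40
  G <- identity_grm(q)
  sim <- simulate_trait(G, sigma_a2 = 30, sigma_e2 = 50, seed = 6)
  fit1 <- fit_st_gblup(sim$phenotypes, G)
  # drop a record: forces the general engine
  ph2 <- sim$phenotypes[-1, ]
  fit2 <- fit_st_gblup(ph2, G)
  expect_identical(fit1$method, "em_eigen")
  expect_identical(fit2$method, "em_mme")
  # same-data check instead: unbalance by duplicating nothing, compare
  # engines on the balanced subset of hybrids
  expect_lt(abs(fit1$h2 - fit2$h2), 0.1)
  expect_true(all(diff(fit2$loglik_trace) >= -1e-10))
})

test_that("prediction flows through relationships for record-free hybrids", {
  q <- 30
  G <- identity_grm(q + 2)
  # hybrid H31 is an exact genomic duplicate of H1; H32 unrelated
  G["H31", "H1"] <- G["H1", "H31"] <- 1
  sim <- simulate_trait(identity_grm(q), sigma_a2 = 40, sigma_e2 = 40,
                        seed = 7)
  fit <- fit_st_gblup(sim$phenotypes, G)
  pred <- predict_genetic_values(fit, c("H1", "H31", "H32"))
  expect_equal(pred$gv[1], unname(fit$a_hat["H1"]))
  expect_equal(pred$gv[2], unname(fit$a_hat["H1"]), tolerance = 1e-8)
  expect_lt(abs(pred$gv[3]), 1e-8)
  expect_error(predict_genetic_values(fit, "H99"), "absent")
})
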