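test_that("QC removes markers in threshold order with correct attribution", {
  # 20 individuals; build columns violating one filter each
  set.seed(7)
  good <- matrix(rep(c(0, 2), 10), 20, 5)
  colnames(good) <- paste0("g", 1:5)
  g_miss <- c(rep(NA, 4), rep(0, 8), rep(2, 8))          # 20% missing
  g_lowmaf <- rep(0, 20)                                 # monomorphic
  g_het <- c(rep(1, 2), rep(0, 9), rep(2, 9))            # 10% het
  g <- cbind(good, miss = g_miss, lowmaf = g_lowmaf, het = g_het)
  res <- qc_markers(g)
  expect_equal(res$report$removed_missing, "miss")
  expect_equal(res$report$removed_maf, "lowmaf")
  expect_equal(res$report$removed_het, "het")
  expect_equal(res$report$n_retained, 5)
  expect_equal(res$report$n_input_markers,
               res$report$n_retained + res$report$n_removed_missing +
                 res$report$n_removed_maf + res$report$n_removed_het)
  # a marker failing both missingness and MAF is attributed to missingness
  g2 <- cbind(good, both = c(rep(NA, 10), rep(0, 10)))
  res2 <- qc_markers(g2)
  expect_equal(res2$report$removed_missing, "both")
  expect_equal(res2$report$n_removed_maf, 0)
})

test_that("QC errors when every marker is removed", {
  g <- matrix(0, 10, 3)  # all monomorphic
  expect_error(qc_markers(g), "empty")
})

test_that("mode imputation fills missing calls, ties broken low", {
  g2 <- cbind(a = c(0, 0, 2, NA), b = c(0, 0, 2, NA), d = c(0, 1, 2, 2))
  out <- impute_mode(g2)
  expect_equal(unname(out[4, "a"]), 0)     # clear mode
  expect_equal(unname(out[4, "b"]), 0)     # 0 and 2 tie -> lower code
  expect_equal(unname(out[, "d"]), c(0, 1, 2, 2))  # untouched
  expect_false(anyNA(out))
  five <- cbind(x = c(0, 0, 2, 2, NA))
  expect_equal(unname(impute_mode(five)[5, 1]), 0)
  expect_error(impute_mode(cbind(x = c(NA, NA))), "fully missing")
})

test_that("VanRaden GRM matches an independent brute-force computation", {
  g <- rbind(i1 = c(0, 2, 2, 0), i2 = c(2, 2, 0, 0), i3 = c(0, 0, 2, 2))
  G <- vanraden_grm(g, epsilon = 0)
  # scripted oracle: explicit loops over the formula
  p <- colSums(g) / (2 * nrow(g))
  denom <- 2 * sum(p * (1 - p))
  oracle <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3) {
    s <- 0
    for (k in 1:4) s <- s + (g[i, k] - 2 * p[k]) * (g[j, k] - 2 * p[k])
    oracle[i, j] <- s / denom
  }
  expect_equal(unname(unclass(G)), oracle, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("duplicated individuals share diagonal and off-diagonal entries", {
  set.seed(3)
  g <- simulate_parents(4, 60, seed = 5)
  g <- rbind(g, dup = g[1, ])
  G <- vanraden_grm(g, epsilon = 0)
  expect_equal(G[1, 5], G[1, 1], tolerance = 1e-12)
  expect_equal(G[5, 5], G[1, 1], tolerance = 1e-12)
})

test_that("GRM diagonal of a fully inbred unrelated panel is near 1 + f = 2", {
  g <- simulate_parents(150, 3000, maf_range = c(0.1, 0.5), seed = 21,
                        het_rate = 0)
  G <- vanraden_grm(g)
  expect_equal(mean(diag(G)), 2, tolerance = 0.08)
  off <- G[upper.tri(G)]
  expect_lt(abs(mean(off)), 0.05)
})

test_that("monomorphic-only panel errors", {
  expect_error(vanraden_grm(matrix(2, 3, 4)), "monomorphic")
})

test_that("hybrid relationships average the parental relationships", {
  Gm <- matrix(c(1.8, 0.2, 0.2, 1.9), 2, 2,
               dimnames = list(c("M1", "M2"), c("M1", "M2")))
  Gp <- matrix(c(2.0, 0.4, 0.4, 1.7), 2, 2,
               dimnames = list(c("F1", "F2"), c("F1", "F2")))
  ped <- data.frame(hybrid_id = c("H1", "H2"), mother_id = c("M1", "M2"),
                    father_id = c("F1", "F2"))
  H <- hybrid_grm(Gm, Gp, ped, epsilon = 0)
  expect_equal(H["H1", "H2"], 0.5 * (0.2 + 0.4), tolerance = 1e-12)
  expect_equal(H["H1", "H1"], 0.5 * (1.8 + 2.0), tolerance = 1e-12)
  # two hybrids sharing both parents: off-diagonal equals each diagonal
  ped2 <- data.frame(hybrid_id = c("Ha", "Hb"), mother_id = "M1",
                     father_id = "F1")
  H2 <- hybrid_grm(Gm, Gp, ped2, epsilon = 0)
  expect_equal(H2["Ha", "Hb"], H2["Ha", "Ha"], tolerance = 1e-12)
})

test_that("full-pipeline hybrid GRM equals a scripted pairwise oracle", {
  mat <- simulate_parents(4, 50, seed = 31, prefix = "M")
  pat <- simulate_parents(4, 50, seed = 32, prefix = "F")
  ped <- simulate_hybrids(mat, pat, 8, seed = 33)
  Gm <- vanraden_grm(impute_mode(mat))
  Gp <- vanraden_grm(impute_mode(pat))
  H <- hybrid_grm(Gm, Gp, ped, epsilon = 0)
  for (i in 1:8) for (j in 1:8) {
    expect_equal(H[i, j],
                 0.5 * (Gm[ped$mother_id[i], ped$mother_id[j]] +
                        Gp[ped$father_id[i], ped$father_id[j]]),
                 tolerance = 1e-12)
  }
})

test_that("hybrid GRM is invariant to pedigree ordering and unknown parents error", {
  mat <- simulate_parents(5, 80, seed = 41, prefix = "M")
  pat <- simulate_parents(5, 80, seed = 42, prefix = "F")
  ped <- simulate_hybrids(mat, pat, 10, seed = 43)
  Gm <- vanraden_grm(impute_mode(mat))
  Gp <- vanraden_grm(impute_mode(pat))
  H1 <- hybrid_grm(Gm, Gp, ped)
  perm <- sample(nrow(ped))
  H2 <- hybrid_grm(Gm, Gp, ped[perm, ])
  expect_equal(H1[ped$hybrid_id, ped$hybrid_id],
               H2[ped$hybrid_id, ped$hybrid_id], tolerance = 1e-12)
  bad <- ped
  bad$mother_id[1] <- "nope"
  expect_error(hybrid_grm(Gm, Gp, bad), "pedigree error")
})

test_that("produced GRMs are exactly symmetric and Cholesky-factorizable", {
  mat <- simulate_parents(6, 100, seed = 51, missing_rate = 0.05)
  g <- impute_mode(qc_markers(mat)$genotypes)
  G <- vanraden_grm(g)
  expect_identical(max(abs(G - t(G))), 0)
  expect_silent(chol(G))
  pat <- simulate_parents(6, 100, seed = 52, prefix = "F")
  ped <- simulate_hybrids(mat, pat, 12, seed = 53)
  H <- hybrid_grm(G, vanraden_grm(impute_mode(pat)), ped)
  expect_identical(max(abs(H - t(H))), 0)
  expect_silent(chol(H))
})
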