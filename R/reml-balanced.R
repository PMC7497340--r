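# EM-REML engine for balanced replicated designs.
#
# Covers the three mixed models the package fits, written as one generic
# model on a hybrid x (replicate * slot) response matrix Y:
#
#   y_{h,rep} = mu_rep + Phi a_h + eps_{h,rep}
#
# with a_h ~ N(0, Sigma_a) correlated across hybrids by the relationship
# matrix G (i.e. Var(vec A) = Sigma_a (x) G), and eps i.i.d. across
# (hybrid, replicate) with Var(eps) = R0:
#   - single trait:        slots = 1,        Phi = 1,   R0 = sigma_e2
#   - bivariate traits:    slots = 2 traits, Phi = I2,  R0 = Sigma_e
#   - random regression:   slots = flights,  Phi = spline basis,
#                          R0 = Phi Sigma_pe Phi' + diag(resid_vars)
#     (the plot-level permanent-environment effect is absorbed into R0 and
#      recovered in the E-step).
#
# After rotating hybrids into the eigenbasis of G, records decompose into
# independent per-eigenvalue blocks of size (reps * slots), so every EM
# iteration is a set of vectorized O(q) updates: no large linear system is
# ever formed. The restricted log-likelihood is monotone non-decreasing
# across iterations (EM property), which the test suite asserts.

balanced_em_reml <- function(Y, G, Phi, model = c("st", "mt", "rr"),
                             Sigma_a, R_par, tol = 1e-8, par_tol = 1e-6,
                             max_iter = 500L) {
  model <- match.arg(model)
  q <- nrow(G)
  rc <- ncol(Y)
  cc <- nrow(Phi)           # slots per replicate
  m <- ncol(Phi)            # random coefficients per hybrid
  r <- rc / cc              # replicates
  stopifnot(nrow(Y) == q, r == round(r))
  eg <- eigen((G + t(G)) / 2, symmetric = TRUE)
  d <- pmax(eg$values, 1e-10)
  U <- eg$vectors
  Yt <- crossprod(U, Y)                   # rotated responses, q x rc
  cvec <- drop(crossprod(U, rep(1, q)))   # rotated fixed-design scalings
  c2 <- cvec^2
  W <- kronecker(rep(1, r), Phi)          # rc x m
  rep_blocks <- lapply(seq_len(r), function(k) (k - 1) * cc + seq_len(cc))

  build_R0 <- function(R_par) {
    switch(model,
           st = matrix(R_par$sigma_e2, 1, 1),
           mt = R_par$Sigma_e,
           rr = Phi %*% R_par$Sigma_pe %*% t(Phi) + diag(R_par$resid_vars,
                                                         cc))
  }
  par_vec <- function(Sigma_a, R_par) {
    c(Sigma_a[upper.tri(Sigma_a, diag = TRUE)],
      switch(model,
             st = R_par$sigma_e2,
             mt = R_par$Sigma_e[upper.tri(R_par$Sigma_e, diag = TRUE)],
             rr = c(R_par$Sigma_pe[upper.tri(R_par$Sigma_pe, diag = TRUE)],
                    R_par$resid_vars)))
  }

  ll_trace <- numeric(0)
  converged <- FALSE
  n_bend <- 0L
  iter_out <- 0L
  mu_hat <- NULL; Ahat_rot <- NULL; avgEps <- NULL; Ehat <- NULL
  for (iter in seq_len(max_iter)) {
    R0 <- build_R0(R_par)
    C0 <- kronecker(diag(r), R0)
    Rch <- chol(C0)
    Aq <- W %*% Sigma_a %*% t(W)
    tmp <- backsolve(Rch, Aq, transpose = TRUE)
    Bt <- t(backsolve(Rch, t(tmp), transpose = TRUE))
    ee <- eigen((Bt + t(Bt)) / 2, symmetric = TRUE)
    lam <- pmax(ee$values, 0)
    Tm <- backsolve(Rch, ee$vectors)      # V_i^{-1} = Tm Gam_i Tm'
    Ys <- Yt %*% Tm
    Gam <- 1 / (1 + outer(d, lam))        # q x rc
    Dx <- colSums(c2 * Gam)
    s <- colSums(cvec * Ys * Gam)
    tmu <- s / Dx
    mu_hat <- drop(t(Rch) %*% (ee$vectors %*% tmu))
    rho <- Ys - outer(cvec, tmu)
    H <- crossprod(Tm, W)                 # rc x m
    ld_rch <- sum(log(diag(Rch)))
    ll <- -0.5 * (q * 2 * ld_rch + sum(log1p(outer(d, lam))) +
                  (-2 * ld_rch + sum(log(Dx))) + sum(rho^2 * Gam))
    ll_trace <- c(ll_trace, ll)

    GR <- rho * Gam
    Ahat_rot <- (d * GR) %*% H %*% Sigma_a          # q x m
    # E-step sums for the coefficient covariance
    w1 <- colSums(d * Gam)
    w2 <- colSums(c2 * d * Gam^2) / Dx
    SH <- Sigma_a %*% t(H)                          # m x rc
    S_a <- crossprod(Ahat_rot, Ahat_rot / d) + q * Sigma_a -
      SH %*% (w1 * t(SH)) + SH %*% (w2 * t(SH))
    Sigma_a_new <- (S_a + t(S_a)) / (2 * q)

    # E-step average residual-block second moment (slots x slots)
    Ehat <- Y - matrix(mu_hat, q, rc, byrow = TRUE) -
      (U %*% Ahat_rot) %*% t(W)
    Mhat <- Reduce(`+`, lapply(rep_blocks, function(b)
      crossprod(Ehat[, b, drop = FALSE]))) / (q * r)
    v1 <- colSums(d^2 * Gam)
    term_pev0 <- (Phi %*% (sum(d) * Sigma_a - SH %*% (v1 * t(SH))) %*%
                    t(Phi)) / q
    Tinv <- crossprod(ee$vectors, Rch)              # Tm^{-1}
    Vb <- t(Tinv) %*% ((1 / Dx) * Tinv)
    w4 <- colSums(c2 * d * Gam) / Dx
    w5 <- colSums(c2 * d^2 * Gam^2) / Dx
    WS <- W %*% Sigma_a %*% t(H)                    # rc x rc
    M2 <- sum(c2) * Vb - WS %*% (w4 * Tinv) -
      t(WS %*% (w4 * Tinv)) + WS %*% (w5 * t(W %*% Sigma_a %*% t(H)))
    avgVar2 <- Reduce(`+`, lapply(rep_blocks, function(b)
      M2[b, b, drop = FALSE])) / (q * r)
    avgEps <- (Mhat + term_pev0 + avgVar2 + t(Mhat + term_pev0 + avgVar2)) / 2

    R_par_new <- switch(model,
      st = list(sigma_e2 = max(avgEps[1, 1], 1e-12)),
      mt = {
        be <- bend_psd(avgEps)
        if (be$bent) n_bend <- n_bend + 1L
        list(Sigma_e = be$matrix)
      },
      rr = {
        R0inv <- chol2inv(chol(R0))
        A_pe <- R_par$Sigma_pe %*% t(Phi) %*% R0inv
        Schur <- R_par$Sigma_pe - A_pe %*% Phi %*% R_par$Sigma_pe
        Epe <- Schur + A_pe %*% avgEps %*% t(A_pe)
        be <- bend_psd((Epe + t(Epe)) / 2)
        if (be$bent) n_bend <- n_bend + 1L
        Cpe <- A_pe %*% avgEps
        Eee <- avgEps - Phi %*% Cpe - t(Phi %*% Cpe) +
          Phi %*% be$matrix %*% t(Phi)
        list(Sigma_pe = be$matrix,
             resid_vars = pmax(diag(Eee), 1e-12))
      })
    ba <- bend_psd(Sigma_a_new)
    if (ba$bent) n_bend <- n_bend + 1L
    Sigma_a_new <- ba$matrix

    old <- par_vec(Sigma_a, R_par)
    new <- par_vec(Sigma_a_new, R_par_new)
    rel <- max(abs(new - old) / pmax(abs(old), 1e-10))
    dll <- if (iter > 1) ll - ll_trace[iter - 1] else Inf
    Sigma_a <- Sigma_a_new
    R_par <- R_par_new
    iter_out <- iter
    if (iter > 1 && abs(dll) < tol * (1 + abs(ll)) && rel < par_tol) {
      converged <- TRUE
      break
    }
  }

  # final E-step quantities at the converged estimates
  R0 <- build_R0(R_par)
  pe_hat <- NULL
  if (model == "rr") {
    A_pe <- R_par$Sigma_pe %*% t(Phi) %*% chol2inv(chol(R0))
    pe_hat <- lapply(rep_blocks, function(b)
      Ehat[, b, drop = FALSE] %*% t(A_pe))
  }
  list(Sigma_a = Sigma_a, R_par = R_par, mu_hat = mu_hat,
       a_hat = U %*% Ahat_rot, pe_hat = pe_hat,
       loglik = ll_trace[length(ll_trace)], loglik_trace = ll_trace,
       converged = converged, n_iter = iter_out, n_bend = n_bend)
}
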