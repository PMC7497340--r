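# EM-REML via Henderson's mixed-model equations for unbalanced records.
#
# Handles one or two traits with arbitrary per-plot record patterns: the
# residual covariance between the two traits contributes only for plots on
# which both are recorded (singleton records carry the marginal residual
# variance), which is the standard unbalanced multi-trait treatment. Missing
# trait records are handled inside EM as latent data, so the residual update
# stays in closed form and the restricted log-likelihood is monotone.
#
# Every record row of the model matrix has exactly two nonzeros (its fixed
# replicate-by-trait cell and its hybrid-by-trait coefficient), so the
# coefficient matrix is assembled by index accumulation and prediction-error
# (co)variances are read off the inverse by direct indexing.

general_em_reml <- function(records, G, n_traits, Sigma_g, Sigma_e,
                            tol = 1e-8, par_tol = 1e-6, max_iter = 500L) {
  hybrids <- rownames(G)
  q <- nrow(G)
  n <- nrow(records)
  stopifnot(all(records$trait %in% seq_len(n_traits)))
  hyb_idx <- match(records$hybrid_id, hybrids)
  if (anyNA(hyb_idx))
    stop("records contain hybrids absent from G", call. = FALSE)
  cell <- interaction(records$trait, records$replicate, drop = TRUE)
  p <- nlevels(cell)
  cell_i <- as.integer(cell)
  rand_i <- p + (records$trait - 1L) * q + hyb_idx
  dim_c <- p + n_traits * q
  y <- records$value

  # residual pattern: joint plots carry both traits
  joint <- NULL
  if (n_traits == 2) {
    t1 <- which(records$trait == 1L)
    t2 <- which(records$trait == 2L)
    k1 <- paste(records$plot_id[t1])
    k2 <- paste(records$plot_id[t2])
    if (anyDuplicated(k1) || anyDuplicated(k2))
      stop("duplicate (plot, trait) records", call. = FALSE)
    mm <- match(k1, k2)
    joint <- cbind(t1[!is.na(mm)], t2[mm[!is.na(mm)]])
    single1 <- t1[is.na(mm)]
    single2 <- setdiff(t2, joint[, 2])
    if (nrow(joint) < 3)
      stop("fewer than 3 jointly recorded plots; residual covariance is not estimable",
           call. = FALSE)
  } else {
    single1 <- seq_len(n)
    single2 <- integer(0)
    joint <- matrix(integer(0), 0, 2)
  }

  Ginv <- chol2inv(chol(G))
  ldetG <- 2 * sum(log(diag(chol(G))))

  accumulate <- function(ii, jj, ww, Cm) {
    lin <- (jj - 1) * dim_c + ii
    agg <- rowsum(ww, lin)
    pos <- as.integer(rownames(agg))
    Cm[pos] <- Cm[pos] + agg[, 1]
    Cm
  }
  # data cross-products for one weight set
  xtx_w <- function(rows_i, rows_j, w) {
    # sum_j w * (e_ci + e_ri)(e_cj + e_rj)' over paired rows
    Cm <- matrix(0, dim_c, dim_c)
    ii <- c(cell_i[rows_i], cell_i[rows_i], rand_i[rows_i], rand_i[rows_i])
    jj <- c(cell_i[rows_j], rand_i[rows_j], cell_i[rows_j], rand_i[rows_j])
    accumulate(ii, jj, rep(w, 4 * length(rows_i)), Cm)
  }
  xty_w <- function(rows_i, rows_j, w) {
    v <- numeric(dim_c)
    contrib <- w * y[rows_j]
    for (ix in list(cell_i[rows_i], rand_i[rows_i])) {
      agg <- rowsum(contrib, ix)
      pos <- as.integer(rownames(agg))
      v[pos] <- v[pos] + agg[, 1]
    }
    v
  }

  # precompute structural pieces (weights change, patterns do not)
  J1 <- joint[, 1]; J2 <- joint[, 2]
  CP <- list(
    j11 = if (length(J1)) xtx_w(J1, J1, 1) else matrix(0, dim_c, dim_c),
    j22 = if (length(J2)) xtx_w(J2, J2, 1) else matrix(0, dim_c, dim_c),
    j12 = if (length(J1)) xtx_w(J1, J2, 1) else matrix(0, dim_c, dim_c),
    s1 = if (length(single1)) xtx_w(single1, single1, 1)
         else matrix(0, dim_c, dim_c),
    s2 = if (length(single2)) xtx_w(single2, single2, 1)
         else matrix(0, dim_c, dim_c))
  VP <- list(
    j1_y1 = if (length(J1)) xty_w(J1, J1, 1) else numeric(dim_c),
    j2_y2 = if (length(J2)) xty_w(J2, J2, 1) else numeric(dim_c),
    j1_y2 = if (length(J1)) xty_w(J1, J2, 1) else numeric(dim_c),
    j2_y1 = if (length(J2)) xty_w(J2, J1, 1) else numeric(dim_c),
    s1 = if (length(single1)) xty_w(single1, single1, 1) else numeric(dim_c),
    s2 = if (length(single2)) xty_w(single2, single2, 1) else numeric(dim_c))
  SS <- list(j11 = sum(y[J1]^2), j22 = sum(y[J2]^2), j12 = sum(y[J1] * y[J2]),
             s1 = sum(y[single1]^2), s2 = sum(y[single2]^2))

  par_vec <- function(Sg, Se) c(Sg[upper.tri(Sg, diag = TRUE)],
                                Se[upper.tri(Se, diag = TRUE)])
  rand_block <- function(t_) (p + (t_ - 1L) * q) + seq_len(q)

  ll_trace <- numeric(0)
  converged <- FALSE
  n_bend <- 0L
  theta <- NULL
  for (iter in seq_len(max_iter)) {
    Sei <- chol2inv(chol(Sigma_e))
    if (n_traits == 2) {
      w11 <- Sei[1, 1]; w22 <- Sei[2, 2]; w12 <- Sei[1, 2]
      C <- w11 * CP$j11 + w22 * CP$j22 + w12 * (CP$j12 + t(CP$j12)) +
        CP$s1 / Sigma_e[1, 1] + CP$s2 / Sigma_e[2, 2]
      rhs <- w11 * VP$j1_y1 + w22 * VP$j2_y2 + w12 * (VP$j1_y2 + VP$j2_y1) +
        VP$s1 / Sigma_e[1, 1] + VP$s2 / Sigma_e[2, 2]
      yRy <- w11 * SS$j11 + w22 * SS$j22 + 2 * w12 * SS$j12 +
        SS$s1 / Sigma_e[1, 1] + SS$s2 / Sigma_e[2, 2]
      ldetR <- nrow(joint) * determinant_log(Sigma_e) +
        length(single1) * log(Sigma_e[1, 1]) +
        length(single2) * log(Sigma_e[2, 2])
    } else {
      C <- CP$s1 / Sigma_e[1, 1]
      rhs <- VP$s1 / Sigma_e[1, 1]
      yRy <- SS$s1 / Sigma_e[1, 1]
      ldetR <- n * log(Sigma_e[1, 1])
    }
    Sgi <- chol2inv(chol(Sigma_g))
    for (t1_ in seq_len(n_traits)) for (t2_ in seq_len(n_traits)) {
      rb <- rand_block(t1_); cb <- rand_block(t2_)
      C[rb, cb] <- C[rb, cb] + Sgi[t1_, t2_] * Ginv
    }
    ch <- chol(C)
    ldetC <- 2 * sum(log(diag(ch)))
    Cinv <- chol2inv(ch)
    theta <- drop(Cinv %*% rhs)
    yPy <- yRy - sum(theta * rhs)
    ll <- -0.5 * (ldetR + q * determinant_log(Sigma_g) +
                  n_traits * ldetG + ldetC + yPy)
    ll_trace <- c(ll_trace, ll)

    # genetic covariance update
    Ahat <- matrix(theta[(p + 1):dim_c], q, n_traits)
    Tmat <- matrix(0, n_traits, n_traits)
    for (t1_ in seq_len(n_traits)) for (t2_ in seq_len(n_traits))
      Tmat[t1_, t2_] <- sum(Ginv * Cinv[rand_block(t1_), rand_block(t2_)])
    Sg_new <- (crossprod(Ahat, Ginv %*% Ahat) + Tmat) / q
    bg <- bend_psd((Sg_new + t(Sg_new)) / 2)
    if (bg$bent) n_bend <- n_bend + 1L
    Sg_new <- bg$matrix

    # residual update (latent-record EM: missing trait imputed per plot)
    ehat <- y - theta[cell_i] - theta[rand_i]
    pev_pair <- function(ri, rj) {
      Cinv[cbind(cell_i[ri], cell_i[rj])] +
        Cinv[cbind(cell_i[ri], rand_i[rj])] +
        Cinv[cbind(rand_i[ri], cell_i[rj])] +
        Cinv[cbind(rand_i[ri], rand_i[rj])]
    }
    if (n_traits == 2) {
      E11 <- sum(ehat[J1]^2 + pev_pair(J1, J1))
      E22 <- sum(ehat[J2]^2 + pev_pair(J2, J2))
      E12 <- sum(ehat[J1] * ehat[J2] + pev_pair(J1, J2))
      if (length(single1)) {
        mo <- ehat[single1]^2 + pev_pair(single1, single1)
        ratio <- Sigma_e[1, 2] / Sigma_e[1, 1]
        E11 <- E11 + sum(mo)
        E12 <- E12 + ratio * sum(mo)
        E22 <- E22 + length(single1) *
          (Sigma_e[2, 2] - Sigma_e[1, 2]^2 / Sigma_e[1, 1]) +
          ratio^2 * sum(mo)
      }
      if (length(single2)) {
        mo <- ehat[single2]^2 + pev_pair(single2, single2)
        ratio <- Sigma_e[1, 2] / Sigma_e[2, 2]
        E22 <- E22 + sum(mo)
        E12 <- E12 + ratio * sum(mo)
        E11 <- E11 + length(single2) *
          (Sigma_e[1, 1] - Sigma_e[1, 2]^2 / Sigma_e[2, 2]) +
          ratio^2 * sum(mo)
      }
      n_plots <- nrow(joint) + length(single1) + length(single2)
      Se_new <- matrix(c(E11, E12, E12, E22), 2, 2) / n_plots
      be <- bend_psd(Se_new)
      if (be$bent) n_bend <- n_bend + 1L
      Se_new <- be$matrix
    } else {
      Se_new <- matrix(max(mean(ehat^2 + pev_pair(seq_len(n),
                                                  seq_len(n))), 1e-12), 1, 1)
    }

    old <- par_vec(Sigma_g, Sigma_e)
    new <- par_vec(Sg_new, Se_new)
    rel <- max(abs(new - old) / pmax(abs(old), 1e-10))
    dll <- if (iter > 1) ll - ll_trace[iter - 1] else Inf
    Sigma_g <- Sg_new
    Sigma_e <- Se_new
    if (iter > 1 && abs(dll) < tol * (1 + abs(ll)) && rel < par_tol) {
      converged <- TRUE
      break
    }
  }

  Ahat <- matrix(theta[(p + 1):dim_c], q, n_traits,
                 dimnames = list(hybrids, NULL))
  b_hat <- theta[seq_len(p)]
  names(b_hat) <- levels(cell)
  list(Sigma_g = Sigma_g, Sigma_e = Sigma_e, a_hat = Ahat, b_hat = b_hat,
       loglik = ll_trace[length(ll_trace)], loglik_trace = ll_trace,
       converged = converged, n_iter = length(ll_trace), n_bend = n_bend)
}

determinant_log <- function(S) {
  as.numeric(determinant(S, logarithm = TRUE)$modulus)
}
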