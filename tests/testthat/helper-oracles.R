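# Independent oracles used across the suite. These are deliberately
# textbook implementations, kept separate from the package's code paths.

# Closed-form Kalman filter + Rauch-Tung-Striebel smoother for the linear
# Gaussian system x_t = A x_{t-1} + w, y_t = H x_t + v.
kalman_oracle <- function(ys, A, H, Q, R, x0, P0) {
  d <- length(x0); nT <- length(ys)
  m <- x0; P <- P0
  mf <- matrix(0, d, nT); Pf <- array(0, c(d, d, nT))
  mp <- mf; Pp <- Pf
  for (t in seq_len(nT)) {
    mpre <- drop(A %*% m); Ppre <- A %*% P %*% t(A) + Q
    S <- drop(H %*% Ppre %*% t(H)) + R
    K <- Ppre %*% t(H) / S
    m <- mpre + drop(K) * (ys[t] - drop(H %*% mpre))
    P <- Ppre - K %*% H %*% Ppre
    mf[, t] <- m; Pf[, , t] <- P; mp[, t] <- mpre; Pp[, , t] <- Ppre
  }
  ms <- mf; Ps <- Pf
  if (nT > 1) {
    for (k in (nT - 1):1) {
      G <- Pf[, , k] %*% t(A) %*% solve(Pp[, , k + 1])
      ms[, k] <- mf[, k] + G %*% (ms[, k + 1] - mp[, k + 1])
      Ps[, , k] <- Pf[, , k] + G %*% (Ps[, , k + 1] - Pp[, , k + 1]) %*% t(G)
    }
  }
  list(mf = mf, Pf = Pf, ms = ms, Ps = Ps)
}

# random linear-Gaussian system + simulated observations
random_lgss <- function(seed, d = 3, nT = 30) {
  set.seed(seed)
  A <- matrix(rnorm(d * d, sd = 0.3), d); diag(A) <- runif(d, 0.5, 0.9)
  H <- matrix(rnorm(d), 1)
  Q <- crossprod(matrix(rnorm(d * d), d)) * 0.02
  R <- runif(1, 0.01, 0.2)
  x0 <- rnorm(d); P0 <- diag(runif(d, 0.2, 1))
  x <- x0; ys <- numeric(nT)
  for (t in seq_len(nT)) {
    x <- drop(A %*% x) + drop(crossprod(chol(Q), rnorm(d)))
    ys[t] <- drop(H %*% x) + rnorm(1, sd = sqrt(R))
  }
  list(A = A, H = H, Q = Q, R = R, x0 = x0, P0 = P0, ys = ys)
}

# run the package's cubature filter/smoother on a linear system
ckf_on_lgss <- function(sys) {
  model <- state_space_model(function(X, u, dt) sys$A %*% X,
                             function(X) drop(sys$H %*% X),
                             sys$x0, sys$P0)
  ckf_smooth(ckf_filter(bold_ts(sys$ys, TR = 1), model,
                        noise_spec(sys$Q, sys$R), upsample_factor = 1))
}

# brute-force causal convolution sum followed by decimation
brute_convolve <- function(x, k, dt, out_TR) {
  n <- length(x)
  full <- vapply(seq_len(n), function(t)
    sum(x[seq_len(t)] * k[t - seq_len(t) + 1], na.rm = TRUE) * dt, 0)
  full[is.na(full)] <- 0
  full[seq(1, n, by = round(out_TR / dt))]
}

# brute-force Tucker reconstruction by explicit summation over the core
brute_tucker_reconstruct <- function(core, factors) {
  d <- vapply(factors, nrow, 1L)
  r <- dim(core)
  out <- array(0, d)
  idx <- as.matrix(expand.grid(lapply(d, seq_len)))
  ridx <- as.matrix(expand.grid(lapply(r, seq_len)))
  for (i in seq_len(nrow(idx))) {
    s <- 0
    for (j in seq_len(nrow(ridx))) {
      term <- core[matrix(ridx[j, ], 1)]
      for (m in seq_along(d)) term <- term * factors[[m]][idx[i, m], ridx[j, m]]
      s <- s + term
    }
    out[matrix(idx[i, ], 1)] <- s
  }
  out
}

# simulate one voxel's BOLD from a boxcar neuronal input (ground truth for
# deconvolution tests)
boxcar_voxel <- function(theta, snr_db, seed, nsec = 200, dt = 0.25, TR = 1) {
  tgrid <- seq(dt, nsec, by = dt)
  boxcar <- as.numeric((tgrid %% 30) < 15)
  b <- simulate_hemodynamics(neuronal_ts(boxcar, dt), theta, noise_sd = 0)
  dec <- round(TR / dt)
  sig <- b$values[seq(dec, length(b$values), by = dec)]
  set.seed(seed)
  y <- sig + rnorm(length(sig), sd = sqrt(var(sig) / 10^(snr_db / 10)))
  list(bold = bold_ts(y, TR), clean = sig, true_n = boxcar,
       boxcar_tr = as.numeric((seq(TR, nsec, by = TR) %% 30) < 15))
}
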