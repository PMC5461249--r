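# Higher-order partial least squares (HOPLS): latent regression between two
# tensors that share their first (trial) mode. Each component consists of a
# common unit-norm latent trial score t_r, orthonormal loading matrices
# P_r / Q_r on the remaining modes of X and Y, and small core tensors
# G_r / D_r that absorb the regression scale. Components are extracted
# greedily from the rank-(L, K) multilinear SVD of the mode-1 cross
# covariance of the current residuals, and both residuals are deflated by
# the fitted rank-(1, L...) / rank-(1, K...) term.
#
# pls_fit() is the two-way specialization (covariance-maximizing PLS with
# rank-one deflation); hopls_fit() on tensors with singleton trailing modes
# reproduces it exactly, which the test suite uses as an oracle.

#' Covariance-maximizing partial least squares (matrix case)
#'
#' For each of `R` components: takes the leading singular pair (w, c) of the
#' residual cross covariance `t(E) %*% F`, forms the unit-norm score
#' `t = E w / ||E w||`, the regression weight `d = t' F c`, and deflates both
#' residuals by the fitted rank-one terms. This is the matrix specialization
#' of [hopls_fit()] and serves as its oracle in the matrix case.
#'
#' @param X Predictor matrix (trials x p).
#' @param Y Response matrix (trials x q).
#' @param R Number of latent components.
#' @return A `pls_model` with score matrices `T`, `U`, weights `W`, `C`,
#'   diagonal regression coefficients `d`, and residual norms per component.
#' @export
pls_fit <- function(X, Y, R) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) stop("X and Y must have the same number of rows (trials)")
  if (R < 1) stop("R must be >= 1")
  if (R > qr(X)$rank) stop("R exceeds the rank of X")
  E <- X; F_ <- Y
  W <- matrix(0, ncol(X), R); Cq <- matrix(0, ncol(Y), R)
  Tm <- matrix(0, nrow(X), R); Um <- matrix(0, nrow(Y), R)
  d <- numeric(R); g <- numeric(R)
  res <- matrix(0, R, 2, dimnames = list(NULL, c("E", "F")))
  for (r in seq_len(R)) {
    Cmat <- crossprod(E, F_)
    sv <- svd(Cmat, nu = 1, nv = 1)
    w <- fix_signs(sv$u); cc <- sv$v
    # carry c's sign with w so the pair keeps the sign of the singular value
    if (crossprod(w, sv$u) < 0) cc <- -cc
    tvec <- E %*% w
    nt <- sqrt(sum(tvec^2))
    if (nt < 1e-12 || sv$d[1] < 1e-14 * max(1, sum(abs(Cmat)))) {
      warning(sprintf("degenerate cross covariance at component %d; returning %d components", r, r - 1))
      keep <- seq_len(r - 1)
      return(structure(list(T = Tm[, keep, drop = FALSE], U = Um[, keep, drop = FALSE],
                            W = W[, keep, drop = FALSE], C = Cq[, keep, drop = FALSE],
                            d = d[keep], g = g[keep], R = r - 1L,
                            residual_norms = res[keep, , drop = FALSE]),
                       class = "pls_model"))
    }
    tvec <- tvec / nt
    u <- F_ %*% cc
    dr <- drop(crossprod(tvec, u))
    E <- E - tvec %*% (nt * t(w))
    F_ <- F_ - tvec %*% (dr * t(cc))
    W[, r] <- w; Cq[, r] <- cc; Tm[, r] <- tvec; Um[, r] <- u
    d[r] <- dr; g[r] <- nt
    res[r, ] <- c(sqrt(sum(E^2)), sqrt(sum(F_^2)))
  }
  structure(list(T = Tm, U = Um, W = W, C = Cq, d = d, g = g, R = as.integer(R),
                 residual_norms = res),
            class = "pls_model")
}

#' Predict responses from a fitted PLS model
#'
#' @param model A `pls_model`.
#' @param X_new New predictor matrix with the training column count.
#' @return Predicted response matrix.
#' @export
pls_predict <- function(model, X_new) {
  X_new <- as.matrix(X_new)
  if (ncol(X_new) != nrow(model$W)) stop("X_new column count does not match training data")
  E <- X_new
  Yp <- matrix(0, nrow(X_new), nrow(model$C))
  for (r in seq_len(model$R)) {
    tvec <- (E %*% model$W[, r]) / model$g[r]
    E <- E - tvec %*% (model$g[r] * t(model$W[, r]))
    Yp <- Yp + tvec %*% (model$d[r] * t(model$C[, r]))
  }
  Yp
}

# coerce a tfr_tensor or array to a plain array
as_tensor_array <- function(x) {
  if (inherits(x, "tfr_tensor")) x$data else x
}

#' Fit a higher-order PLS model between two tensors sharing mode 1
#'
#' For each component r: the mode-1 cross covariance of the current X and Y
#' residuals is formed (a tensor over the non-trial modes of both sides) and
#' its rank-(L, K) orthogonal approximation is taken via the multilinear SVD,
#' yielding loading matrices `P_r` (X side) and `Q_r` (Y side). The common
#' latent vector `t_r` is the dominant left singular vector of the X residual
#' projected onto `P_r`; core tensors `G_r`, `D_r` are the projections of the
#' residuals onto `(t_r, P_r)` and `(t_r, Q_r)`; both residuals are then
#' deflated by the fitted terms. The fit is deterministic for fixed input.
#'
#' @param X Predictor tensor (`tfr_tensor` or array), trials on mode 1.
#' @param Y Response tensor, same mode-1 length as `X`.
#' @param R Number of latent components.
#' @param L Integer vector of X-side subspace ranks, one per mode 2..N.
#' @param K Integer vector of Y-side subspace ranks, one per mode 2..M.
#' @return A `hopls_model` with per-component scores `T` (columns `t_r`,
#'   unit norm), loading lists `P`, `Q`, core lists `G`, `D`, and residual
#'   norms per component.
#' @export
hopls_fit <- function(X, Y, R, L, K) {
  Xa <- as_tensor_array(X); Ya <- as_tensor_array(Y)
  dx <- dim(Xa); dy <- dim(Ya)
  if (dx[1] != dy[1])
    stop("mode-1 coupling violated: X and Y must have the same number of trials")
  if (length(L) != length(dx) - 1 || length(K) != length(dy) - 1)
    stop("L and K must give one rank per non-trial mode")
  if (any(L < 1) || any(L > dx[-1]) || any(K < 1) || any(K > dy[-1]))
    stop("subspace ranks must lie within the mode dimensions")
  if (R < 1) stop("R must be >= 1")
  E <- Xa; F_ <- Ya
  nX <- length(dx); nY <- length(dy)
  P <- vector("list", R); Q <- vector("list", R)
  G <- vector("list", R); D <- vector("list", R)
  Tm <- matrix(0, dx[1], R)
  res <- matrix(0, R, 2, dimnames = list(NULL, c("E", "F")))
  tolC <- 1e-12 * max(tnorm(Xa) * tnorm(Ya), 1)
  for (r in seq_len(R)) {
    Me <- unfold(E, 1); Mf <- unfold(F_, 1)
    Cmat <- crossprod(Me, Mf)                  # p x q
    if (sqrt(sum(Cmat^2)) <= tolC) {
      warning(sprintf("degenerate cross covariance at component %d; returning %d components", r, r - 1))
      R <- r - 1L
      break
    }
    Ct <- array(Cmat, dim = c(dx[-1], dy[-1]))
    Pr <- vector("list", nX - 1); Qr <- vector("list", nY - 1)
    for (n in seq_len(nX - 1)) {
      un <- unfold(Ct, n)
      Pr[[n]] <- top_eigvecs(tcrossprod(un), L[n])
    }
    for (m in seq_len(nY - 1)) {
      un <- unfold(Ct, (nX - 1) + m)
      Qr[[m]] <- top_eigvecs(tcrossprod(un), K[m])
    }
    Z <- ttml(E, lapply(Pr, t), 2:nX)
    sv <- svd(unfold(Z, 1), nu = 1, nv = 0)
    tvec <- fix_signs(sv$u)
    Gr <- ttml(Z, list(t(tvec)), 1)
    Dr <- ttml(F_, c(list(t(tvec)), lapply(Qr, t)), c(1, 2:nY))
    E <- E - ttml(Gr, c(list(tvec), Pr), c(1, 2:nX))
    F_ <- F_ - ttml(Dr, c(list(tvec), Qr), c(1, 2:nY))
    P[[r]] <- Pr; Q[[r]] <- Qr; G[[r]] <- Gr; D[[r]] <- Dr
    Tm[, r] <- tvec
    res[r, ] <- c(tnorm(E), tnorm(F_))
  }
  keep <- seq_len(R)
  structure(list(R = as.integer(R), T = Tm[, keep, drop = FALSE],
                 P = P[keep], Q = Q[keep], G = G[keep], D = D[keep],
                 L = as.integer(L), K = as.integer(K),
                 dims_X = dx, dims_Y = dy,
                 residual_norms = res[keep, , drop = FALSE]),
            class = "hopls_model")
}

#' Forward-predict the response tensor for new trials
#'
#' Latent scores for the new trials are extracted sequentially from the X
#' side (projection onto `P_r`, regression against the core `G_r`, then
#' deflation), and pushed through the Y-side cores `D_r` and loadings `Q_r`.
#' This is a forward (well-posed) estimation: any number of new trials is
#' allowed, while modes 2..N must match the training dimensions.
#'
#' @param model A `hopls_model` (or `sparse_hopls`).
#' @param X_new Predictor tensor with training modes 2..N.
#' @return Predicted Y array: `dim = c(n_new_trials, trained Y modes 2..M)`.
#' @export
hopls_predict <- function(model, X_new) {
  if (inherits(model, "sparse_hopls")) model <- model$effective
  Xa <- as_tensor_array(X_new)
  dx <- dim(Xa)
  if (!identical(dx[-1], model$dims_X[-1]))
    stop("X_new modes 2..N do not match the training dimensions")
  nX <- length(dx); nY <- length(model$dims_Y)
  E <- Xa
  Yp <- array(0, dim = c(dx[1], model$dims_Y[-1]))
  for (r in seq_len(model$R)) {
    Z <- ttml(E, lapply(model$P[[r]], t), 2:nX)
    gv <- as.numeric(model$G[[r]])
    g2 <- sum(gv^2)
    tvec <- if (g2 > 1e-300) (unfold(Z, 1) %*% gv) / g2 else matrix(0, dx[1], 1)
    E <- E - ttml(model$G[[r]], c(list(tvec), model$P[[r]]), c(1, 2:nX))
    Yp <- Yp + ttml(model$D[[r]], c(list(tvec), model$Q[[r]]), c(1, 2:nY))
  }
  Yp
}

#' Fitted (in-sample) response reconstruction
#'
#' @param model A `hopls_model`.
#' @return The training-set Y reconstruction `sum_r D_r x1 t_r x Q_r`.
#' @export
hopls_fitted <- function(model) {
  nY <- length(model$dims_Y)
  Yp <- array(0, dim = model$dims_Y)
  for (r in seq_len(model$R)) {
    Yp <- Yp + ttml(model$D[[r]], c(list(model$T[, r, drop = FALSE]), model$Q[[r]]),
                    c(1, 2:nY))
  }
  Yp
}

#' @export
print.hopls_model <- function(x, ...) {
  cat("HOPLS model: R =", x$R, " L = (", paste(x$L, collapse = ","),
      ") K = (", paste(x$K, collapse = ","), ")\n")
  cat("trials:", x$dims_X[1], " X modes:", paste(x$dims_X[-1], collapse = "x"),
      " Y modes:", paste(x$dims_Y[-1], collapse = "x"), "\n")
  invisible(x)
}

#' Predictive R-squared of a HOPLS model on held-out data
#'
#' @param model A `hopls_model` or `sparse_hopls`.
#' @param X_new,Y_new Held-out tensors.
#' @return `1 - ||Y - Yhat||^2 / ||Y - mean||^2` (can be negative).
#' @export
hopls_r2 <- function(model, X_new, Y_new) {
  Ya <- as_tensor_array(Y_new)
  Yp <- hopls_predict(model, X_new)
  1 - sum((Ya - Yp)^2) / sum((Ya - mean(Ya))^2)
}

#' Cross-validated predictive R-squared
#'
#' Splits trials into `folds` contiguous-free random folds, fits on the
#' training trials and evaluates [hopls_r2()] on the held-out trials.
#'
#' @param X,Y Tensors sharing mode 1.
#' @param R,L,K HOPLS ranks (see [hopls_fit()]).
#' @param folds Number of folds.
#' @param seed Seed for the fold assignment.
#' @return Mean held-out R-squared across folds.
#' @export
hopls_cv_r2 <- function(X, Y, R, L, K, folds = 5, seed = 1L) {
  Xa <- as_tensor_array(X); Ya <- as_tensor_array(Y)
  n <- dim(Xa)[1]
  fold_id <- with_seed(seed, sample(rep_len(seq_len(folds), n)))
  r2 <- numeric(folds)
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    m <- hopls_fit(index_mode1(Xa, tr), index_mode1(Ya, tr), R, L, K)
    r2[f] <- hopls_r2(m, index_mode1(Xa, !tr), index_mode1(Ya, !tr))
  }
  mean(r2)
}

# subset an array along mode 1, keeping the other modes
index_mode1 <- function(x, idx) {
  d <- dim(x)
  m <- unfold(x, 1)[idx, , drop = FALSE]
  fold(m, 1, c(nrow(m), d[-1]))
}

#' Simulate tensor pairs from a planted HOPLS model
#'
#' Generates `(X, Y)` from `R` planted components with mutually orthogonal
#' loading subspaces across components and geometrically decaying component
#' strengths, plus optional i.i.d. Gaussian noise. With
#' `zero_mean_time = TRUE` the loading columns of the designated time mode
#' are orthogonalized against the constant vector, so the planted linkage is
#' carried purely by within-trial temporal dynamics (the structure targeted
#' by time-shuffling surrogates).
#'
#' @param n_trials Mode-1 length.
#' @param dims_X,dims_Y Non-trial mode dimensions of X and Y.
#' @param R Number of planted components.
#' @param L,K Per-mode subspace ranks of the planted loadings.
#' @param noise_sd Noise standard deviation added to both tensors. Ignored
#'   when `snr_db` is given.
#' @param snr_db If non-`NULL`, per-tensor noise is scaled so the ratio of
#'   planted-signal energy to noise energy equals `snr_db` decibels.
#' @param seed Integer seed.
#' @param zero_mean_time Index of a time mode (within `dims_X`/`dims_Y`,
#'   counting from 1 = first non-trial mode) whose loadings are made
#'   orthogonal to the constant vector, or `NULL` (default) for none.
#' @param strength Leading component strength; component r is scaled by
#'   `strength * decay^(r-1)`.
#' @param decay Geometric strength decay across components.
#' @return List with `X`, `Y` (arrays), the planted `model` pieces
#'   (`T`, `P`, `Q`, `G`, `D`) and the noiseless tensors `X0`, `Y0`.
#' @export
simulate_hopls_data <- function(n_trials, dims_X, dims_Y, R = 3,
                                L = rep(2, length(dims_X)),
                                K = rep(2, length(dims_Y)),
                                noise_sd = 0, seed = 1L, snr_db = NULL,
                                zero_mean_time = NULL,
                                strength = 1, decay = 0.4) {
  stopifnot(all(R * L <= dims_X), all(R * K <= dims_Y))
  with_seed(seed, {
    Tm <- qr.Q(qr(matrix(stats::rnorm(n_trials * R), n_trials, R)))
    orth_block <- function(dims, ranks, zm) {
      lapply(seq_along(dims), function(j) {
        M <- matrix(stats::rnorm(dims[j] * ranks[j] * R), dims[j])
        if (!is.null(zm) && j == zm) M <- M - rep(1, dims[j]) %o% colMeans(M)
        qr.Q(qr(M))  # dims[j] x (ranks[j] * R), orthonormal
      })
    }
    Pall <- orth_block(dims_X, L, zero_mean_time)
    Qall <- orth_block(dims_Y, K, zero_mean_time)
    X0 <- array(0, c(n_trials, dims_X)); Y0 <- array(0, c(n_trials, dims_Y))
    P <- vector("list", R); Q <- vector("list", R)
    G <- vector("list", R); D <- vector("list", R)
    for (r in seq_len(R)) {
      s <- strength * decay^(r - 1)
      P[[r]] <- lapply(seq_along(dims_X), function(j)
        Pall[[j]][, (r - 1) * L[j] + seq_len(L[j]), drop = FALSE])
      Q[[r]] <- lapply(seq_along(dims_Y), function(j)
        Qall[[j]][, (r - 1) * K[j] + seq_len(K[j]), drop = FALSE])
      # near-isotropic cores keep every planted direction at scale s
      G[[r]] <- array(s * diag_core(L), dim = c(1, L))
      D[[r]] <- array(s * diag_core(K), dim = c(1, K))
      X0 <- X0 + ttml(G[[r]], c(list(Tm[, r, drop = FALSE]), P[[r]]),
                      seq_len(length(dims_X) + 1))
      Y0 <- Y0 + ttml(D[[r]], c(list(Tm[, r, drop = FALSE]), Q[[r]]),
                      seq_len(length(dims_Y) + 1))
    }
    X <- X0; Y <- Y0
    sd_x <- noise_sd; sd_y <- noise_sd
    if (!is.null(snr_db)) {
      sd_x <- sqrt(sum(X0^2) / (length(X0) * 10^(snr_db / 10)))
      sd_y <- sqrt(sum(Y0^2) / (length(Y0) * 10^(snr_db / 10)))
    }
    if (sd_x > 0) X <- X + array(stats::rnorm(length(X), sd = sd_x), dim(X))
    if (sd_y > 0) Y <- Y + array(stats::rnorm(length(Y), sd = sd_y), dim(Y))
    list(X = X, Y = Y, X0 = X0, Y0 = Y0,
         model = list(T = Tm, P = P, Q = Q, G = G, D = D))
  })
}

# A well-conditioned core pattern of shape (1, ranks): a "diagonal" through
# the flattened core with slowly varying magnitudes, so all per-mode singular
# values of the component are comparable and nonzero.
diag_core <- function(ranks) {
  len <- prod(ranks)
  v <- numeric(len)
  k <- min(ranks)
  idx <- round(seq(1, len, length.out = k))
  v[idx] <- seq(1, 0.6, length.out = k)
  v
}
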