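test_that("PLS reproduces Y exactly on the identity task at full rank", {
  set.seed(1)
  X <- matrix(rnorm(30 * 6), 30)
  m <- pls_fit(X, X, qr(X)$rank)
  expect_lt(max(abs(pls_predict(m, X) - X)), 1e-8)
})

test_that("PLS recovers a planted diagonal regression", {
  set.seed(2)
  n <- 40
  Tm <- qr.Q(qr(matrix(rnorm(n * 2), n)))
  P <- qr.Q(qr(matrix(rnorm(8 * 2), 8)))
  Q <- qr.Q(qr(matrix(rnorm(5 * 2), 5)))
  d_true <- c(3, 1.2)
  X <- Tm %*% t(P)
  Y <- Tm %*% diag(d_true) %*% t(Q)
  m <- pls_fit(X, Y, 2)
  expect_equal(sort(abs(m$d), decreasing = TRUE), d_true, tolerance = 1e-6)
  expect_error(pls_fit(X, Y, 5), "rank")
})

test_that("PLS predicts at chance on independent data", {
  set.seed(3)
  r2 <- replicate(5, {
    X <- matrix(rnorm(50 * 8), 50); Y <- matrix(rnorm(50 * 6), 50)
    folds <- make_folds(50, 5, seed = 1)
    ss <- vapply(1:5, function(f) {
      m <- pls_fit(X[folds != f, ], Y[folds != f, ], 2)
      Yp <- pls_predict(m, X[folds == f, ])
      Yt <- Y[folds == f, ]
      1 - sum((Yt - Yp)^2) / sum((Yt - mean(Yt))^2)
    }, 0)
    mean(ss)
  })
  expect_lte(median(r2), 0.05)
})

test_that("HOPLS recovers a noiseless planted model exactly", {
  sim <- simulate_hopls_data(40, c(8, 6, 6), c(7, 6, 6), R = 3,
                             L = c(2, 2, 2), K = c(2, 2, 2), seed = 4)
  m <- hopls_fit(sim$X, sim$Y, R = 3, L = c(2, 2, 2), K = c(2, 2, 2))
  expect_lt(tnorm(hopls_fitted(m) - sim$Y) / tnorm(sim$Y), 1e-6)
  # in-sample prediction equals the fitted reconstruction exactly
  expect_lt(max(abs(hopls_predict(m, sim$X) - hopls_fitted(m))), 1e-10)
  # residual norms non-increasing, loadings orthonormal
  expect_true(all(diff(m$residual_norms[, "E"]) <= 1e-10))
  expect_true(all(diff(m$residual_norms[, "F"]) <= 1e-10))
  for (r in 1:3) for (P in m$P[[r]])
    expect_lt(max(abs(crossprod(P) - diag(ncol(P)))), 1e-10)
})

test_that("held-out prediction of a planted model is near-exact", {
  sim <- simulate_hopls_data(60, c(8, 6, 6), c(7, 6, 6), R = 2,
                             L = c(2, 2, 2), K = c(2, 2, 2), seed = 5)
  tr <- 1:40
  m <- hopls_fit(sim$X[tr, , , ], sim$Y[tr, , , ], 2, c(2, 2, 2), c(2, 2, 2))
  Yp <- hopls_predict(m, sim$X[-tr, , , ])
  expect_lt(tnorm(Yp - sim$Y[-tr, , , ]) / tnorm(sim$Y[-tr, , , ]), 1e-4)
  # single-trial shape contract
  one <- hopls_predict(m, sim$X[1, , , , drop = FALSE])
  expect_equal(dim(one), c(1, 7, 6, 6))
})

test_that("tensors with singleton trailing modes reduce to matrix PLS", {
  set.seed(6)
  X <- matrix(rnorm(30 * 6), 30)
  Y <- X %*% matrix(rnorm(6 * 4), 6) + 0.1 * matrix(rnorm(30 * 4), 30)
  pm <- pls_fit(X, Y, 3)
  hm <- hopls_fit(array(X, c(30, 6, 1)), array(Y, c(30, 4, 1)),
                  R = 3, L = c(1, 1), K = c(1, 1))
  expect_lt(max(abs(hopls_predict(hm, array(X, c(30, 6, 1))) -
                    array(pls_predict(pm, X), c(30, 4, 1)))), 1e-6)
})

test_that("HOPLS predicts at chance on unlinked tensors", {
  set.seed(7)
  X <- array(rnorm(40 * 5 * 4), c(40, 5, 4))
  Y <- array(rnorm(40 * 4 * 3), c(40, 4, 3))
  expect_lte(hopls_cv_r2(X, Y, 2, c(2, 2), c(2, 2), seed = 1), 0.05)
})

test_that("planted linkage survives 10 dB noise (median over replicates)", {
  r2 <- vapply(1:20, function(s) {
    sim <- simulate_hopls_data(60, c(8, 6, 6), c(7, 6, 6), R = 2,
                               L = c(2, 2, 2), K = c(2, 2, 2),
                               snr_db = 10, seed = 100 + s)
    tr <- 1:40
    m <- hopls_fit(sim$X[tr, , , ], sim$Y[tr, , , ], 2, c(2, 2, 2), c(2, 2, 2))
    hopls_r2(m, sim$X[-tr, , , ], sim$Y[-tr, , , ])
  }, 0)
  expect_gte(median(r2), 0.5)
})

test_that("coupling and rank contracts are enforced", {
  X <- array(rnorm(20 * 4 * 3), c(20, 4, 3))
  Y <- array(rnorm(19 * 4 * 3), c(19, 4, 3))
  expect_error(hopls_fit(X, Y, 1, c(2, 2), c(2, 2)), "mode-1 coupling")
  Y2 <- array(rnorm(20 * 4 * 3), c(20, 4, 3))
  expect_error(hopls_fit(X, Y2, 1, c(5, 2), c(2, 2)), "ranks")
  m <- hopls_fit(X, Y2, 1, c(2, 2), c(2, 2))
  expect_error(hopls_predict(m, array(rnorm(10 * 5 * 3), c(10, 5, 3))),
               "modes 2..N")
})

test_that("an all-zero response degenerates gracefully", {
  set.seed(8)
  X <- array(rnorm(20 * 4 * 3), c(20, 4, 3))
  Y <- array(0, c(20, 3, 2))
  expect_warning(m <- hopls_fit(X, Y, 2, c(2, 2), c(2, 2)), "degenerate")
  expect_equal(m$R, 0L)
  expect_equal(hopls_predict(m, X), array(0, c(20, 3, 2)))
})
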