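test_that("surrogates preserve per-fiber multisets and are seeded", {
  set.seed(1)
  X <- array(rnorm(6 * 3 * 8 * 4), c(6, 3, 8, 4))
  Y <- array(rnorm(6 * 2 * 5 * 3), c(6, 2, 5, 3))
  s1 <- make_surrogate(X, Y, seed = 7)
  expect_identical(s1$Y, Y)
  for (i in 1:6) for (ch in 1:3) for (fr in 1:4) {
    expect_equal(sort(s1$X[i, ch, , fr]), sort(X[i, ch, , fr]))
  }
  # the same permutation is shared across channels and frequencies
  perm <- match(s1$X[1, 1, , 1], X[1, 1, , 1])
  expect_equal(s1$X[1, 3, , 4], X[1, 3, perm, 4])
  s2 <- make_surrogate(X, Y, seed = 7)
  s3 <- make_surrogate(X, Y, seed = 8)
  expect_identical(s1$X, s2$X)
  expect_false(identical(s1$X, s3$X))
})

test_that("time shuffling destroys a temporally-carried linkage", {
  sim <- simulate_hopls_data(40, c(4, 8, 4), c(4, 8, 4), R = 2,
                             L = c(2, 2, 2), K = c(2, 2, 2), snr_db = 15,
                             seed = 11, zero_mean_time = 2)
  expect_gt(hopls_cv_r2(sim$X, sim$Y, 2, c(2, 2, 2), c(2, 2, 2), seed = 1), 0.5)
  r2s <- vapply(1:20, function(j) {
    s <- make_surrogate(sim$X, sim$Y, seed = j)
    hopls_cv_r2(s$X, s$Y, 2, c(2, 2, 2), c(2, 2, 2), seed = 1)
  }, 0)
  expect_lte(median(r2s), 0.05)
})

test_that("split-half fits recover planted core parameters", {
  sim <- simulate_hopls_data(60, c(4, 6, 4), c(4, 6, 4), R = 2,
                             L = c(2, 2, 2), K = c(2, 2, 2),
                             snr_db = 25, seed = 12)
  sp <- fit_spec(R = 2, L = c(2, 2, 2), K = c(2, 2, 2))
  sh <- split_half_distribution(sim$X, sim$Y, 30, sp, seed = 3)
  med <- apply(sh$params, 2, median)
  ref <- bcilink:::hopls_param_vector(sh$reference, 60)
  # strong (planted, leading-component) parameters reproduce within 10%
  strong <- which(abs(ref) > 0.5 * max(abs(ref)))
  expect_true(all(abs(med[strong] - ref[strong]) <= 0.1 * abs(ref[strong])))
  expect_gt(min(sh$test_r2), 0.5)
  # degenerate single-split case
  sh1 <- split_half_distribution(sim$X, sim$Y, 1, sp, seed = 3)
  expect_equal(nrow(sh1$params), 1)
  expect_error(split_half_distribution(sim$X[1:10, , , ], sim$Y[1:10, , , ],
                                       5, sp), "20 trials")
})

test_that("unlinked data yields chance-level split-half prediction", {
  set.seed(13)
  X <- array(rnorm(40 * 3 * 6 * 3), c(40, 3, 6, 3))
  Y <- array(rnorm(40 * 3 * 5 * 3), c(40, 3, 5, 3))
  sp <- fit_spec(R = 2, L = c(2, 2, 2), K = c(2, 2, 2))
  sh <- split_half_distribution(X, Y, 10, sp, seed = 4)
  expect_lte(median(sh$test_r2), 0.05)
})

test_that("the surrogate null is reproducible and correctly sized", {
  set.seed(14)
  X <- array(rnorm(24 * 3 * 6 * 3), c(24, 3, 6, 3))
  Y <- array(rnorm(24 * 2 * 5 * 2), c(24, 2, 5, 2))
  sp <- fit_spec(R = 1, L = c(2, 2, 2), K = c(2, 2, 2), n_splits = 2)
  n1 <- null_distribution(X, Y, 8, sp, seed = 5)
  n2 <- null_distribution(X, Y, 8, sp, seed = 5)
  expect_identical(n1$parameter_samples, n2$parameter_samples)
  expect_equal(nrow(n1$parameter_samples), 8)
  expect_equal(ncol(n1$parameter_samples), 1 * (8 + 8))
  expect_equal(n1$n_surrogates, 8L)
  expect_equal(formals(null_distribution)$n_surrogates, 10000)
})

test_that("sparsification keeps planted linkage and zeroes alpha = 0", {
  hits <- vapply(1:8, function(rep) {
    sim <- simulate_hopls_data(40, c(4, 8, 4), c(4, 8, 4), R = 2,
                               L = c(2, 2, 2), K = c(2, 2, 2), snr_db = 15,
                               seed = 300 + rep, zero_mean_time = 2)
    sp <- fit_spec(R = 2, L = c(1, 1, 1), K = c(1, 1, 1), n_splits = 3)
    obs <- split_half_distribution(sim$X, sim$Y, 10, sp, seed = rep)
    nl <- null_distribution(sim$X, sim$Y, 120, sp, seed = rep * 13)
    sm <- sparsify(obs, nl, 0.05)
    sum(sm$significance_mask) >= 1
  }, TRUE)
  expect_gte(mean(hits), 0.9)
  # alpha = 0 zeroes everything and predicts the zero tensor
  sim <- simulate_hopls_data(40, c(4, 8, 4), c(4, 8, 4), R = 2,
                             L = c(2, 2, 2), K = c(2, 2, 2), snr_db = 15,
                             seed = 300, zero_mean_time = 2)
  sp <- fit_spec(R = 2, L = c(1, 1, 1), K = c(1, 1, 1), n_splits = 2)
  obs <- split_half_distribution(sim$X, sim$Y, 4, sp, seed = 1)
  nl <- null_distribution(sim$X, sim$Y, 10, sp, seed = 2)
  sm0 <- sparsify(obs, nl, 0)
  expect_true(all(!sm0$significance_mask))
  expect_equal(hopls_predict(sm0, sim$X), array(0, dim(sim$Y)))
})

test_that("sparse model does not underperform the full model on unlinked data", {
  set.seed(15)
  X <- array(rnorm(50 * 3 * 6 * 3), c(50, 3, 6, 3))
  Y <- array(rnorm(50 * 3 * 5 * 3), c(50, 3, 5, 3))
  tr <- 1:34
  sp <- fit_spec(R = 2, L = c(2, 2, 2), K = c(2, 2, 2), n_splits = 3)
  obs <- split_half_distribution(X[tr, , , ], Y[tr, , , ], 6, sp, seed = 6)
  nl <- null_distribution(X[tr, , , ], Y[tr, , , ], 60, sp, seed = 7)
  sm <- sparsify(obs, nl, 0.05)
  Yt <- Y[-tr, , , ]
  err_full <- sum((hopls_predict(sm$base, X[-tr, , , ]) - Yt)^2)
  err_sparse <- sum((hopls_predict(sm, X[-tr, , , ]) - Yt)^2)
  expect_lte(err_sparse, err_full + 1e-9)
})

test_that("mismatched parameter sets are rejected", {
  set.seed(16)
  X <- array(rnorm(24 * 3 * 6 * 3), c(24, 3, 6, 3))
  Y <- array(rnorm(24 * 2 * 5 * 2), c(24, 2, 5, 2))
  sp1 <- fit_spec(R = 1, L = c(2, 2, 2), K = c(2, 2, 2), n_splits = 2)
  sp2 <- fit_spec(R = 1, L = c(1, 1, 1), K = c(1, 1, 1), n_splits = 2)
  obs <- split_half_distribution(X, Y, 3, sp1, seed = 1)
  nl <- null_distribution(X, Y, 5, sp2, seed = 2)
  expect_error(sparsify(obs, nl, 0.05), "different parameter sets")
})
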