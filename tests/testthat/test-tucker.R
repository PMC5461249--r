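test_that("full-rank decomposition is exact", {
  set.seed(1)
  x <- array(rnorm(4 * 5 * 6), c(4, 5, 6))
  m <- tucker_decompose(x, c(4, 5, 6))
  expect_lt(tnorm(tucker_reconstruct(m) - x) / tnorm(x), 1e-10)
  expect_lt(m$fit, 1e-10)
})

test_that("a tensor built from a planted core and factors is recovered", {
  set.seed(2)
  core <- array(rnorm(8), c(2, 2, 2))
  factors <- lapply(c(6, 5, 7), function(d) qr.Q(qr(matrix(rnorm(d * 2), d))))
  x <- ttml(core, factors, 1:3)
  m <- tucker_decompose(x, c(2, 2, 2))
  expect_lt(tnorm(tucker_reconstruct(m) - x) / tnorm(x), 1e-8)
})

test_that("a rank-1 outer product is recovered with collinear factors", {
  set.seed(3)
  a <- rnorm(5); b <- rnorm(4); cc <- rnorm(6)
  x <- a %o% b %o% cc
  m <- tucker_decompose(x, c(1, 1, 1))
  expect_lt(m$fit, 1e-10)
  expect_gt(abs(cor(m$factors[[1]][, 1], a)), 1 - 1e-10)
  expect_gt(abs(cor(m$factors[[2]][, 1], b)), 1 - 1e-10)
  expect_gt(abs(cor(m$factors[[3]][, 1], cc)), 1 - 1e-10)
})

test_that("reconstruction matches the brute-force contraction oracle", {
  set.seed(4)
  m <- tucker_decompose(array(rnorm(3 * 4 * 5), c(3, 4, 5)), c(2, 2, 3))
  expect_lt(max(abs(tucker_reconstruct(m) -
                    brute_tucker_reconstruct(m$core, m$factors))), 1e-12)
  m$core[] <- 0
  expect_equal(tucker_reconstruct(m), array(0, c(3, 4, 5)))
})

test_that("factors are orthonormal with deterministic signs", {
  set.seed(5)
  x <- array(rnorm(5 * 6 * 4), c(5, 6, 4))
  m <- tucker_decompose(x, c(3, 3, 2))
  for (f in m$factors) {
    expect_lt(max(abs(crossprod(f) - diag(ncol(f)))), 1e-10)
    expect_true(all(apply(f, 2, function(col) col[which.max(abs(col))] > 0)))
  }
})

test_that("reconstruction error is monotone in the ranks", {
  set.seed(6)
  for (rep in 1:5) {
    x <- array(rnorm(5 * 5 * 5), c(5, 5, 5))
    fits <- vapply(1:5, function(r) tucker_decompose(x, c(r, 3, 3))$fit, 0)
    expect_true(all(diff(fits) <= 1e-12))
    fits2 <- vapply(1:5, function(r) tucker_decompose(x, c(3, r, 3))$fit, 0)
    expect_true(all(diff(fits2) <= 1e-12))
  }
})

test_that("discarded singular values bracket the reconstruction error", {
  set.seed(7)
  x <- array(rnorm(6 * 5 * 4), c(6, 5, 4))
  ranks <- c(3, 2, 2)
  m <- tucker_decompose(x, ranks)
  err2 <- sum((tucker_reconstruct(m) - x)^2)
  disc <- vapply(1:3, function(n)
    sum(m$mode_sv[[n]][-seq_len(ranks[n])]^2), 0)
  expect_gte(err2 + 1e-10, max(disc))
  expect_lte(err2, sum(disc) + 1e-10)
  # exact at full rank: both sides zero
  mf <- tucker_decompose(x, c(6, 5, 4))
  expect_lt(sum((tucker_reconstruct(mf) - x)^2), 1e-20)
})

test_that("rank validation rejects impossible requests", {
  x <- array(rnorm(24), c(2, 3, 4))
  expect_error(tucker_decompose(x, c(3, 3, 4)), "rank")
  expect_error(tucker_decompose(x, c(2, 3)), "one entry per mode")
})

test_that("sequential updates reproduce the batch decomposition", {
  set.seed(8)
  # structured (low-rank + noise) stream
  core <- array(rnorm(2 * 2 * 2), c(2, 2, 2))
  U <- lapply(c(20, 6, 5), function(d) qr.Q(qr(matrix(rnorm(d * 2), d))))
  x <- ttml(core, U, 1:3) + array(rnorm(20 * 6 * 5, sd = 0.05), c(20, 6, 5))
  st <- tucker_stream(c(6, 5), c(20, 2, 2))
  for (i in 1:20) st <- tucker_update(st, x[i, , ])
  sm <- tucker_stream_model(st)
  bm <- tucker_decompose(x, c(20, 2, 2))
  expect_lt(abs(sm$fit - bm$fit), 0.1 * max(bm$fit, 1e-12))
  for (f in sm$factors) expect_lt(max(abs(crossprod(f) - diag(ncol(f)))), 1e-8)
})

test_that("appending an in-span slice leaves the model unchanged", {
  set.seed(9)
  core <- array(rnorm(2 * 2 * 2), c(2, 2, 2))
  U <- lapply(c(10, 6, 5), function(d) qr.Q(qr(matrix(rnorm(d * 2), d))))
  x <- ttml(core, U, 1:3)   # exact multilinear rank (2,2,2)
  st <- tucker_stream(c(6, 5), c(12, 2, 2))
  for (i in 1:10) st <- tucker_update(st, x[i, , ])
  m0 <- tucker_stream_model(st)
  st2 <- tucker_update(st, x[3, , ])   # duplicate slice: inside every span
  m1 <- tucker_stream_model(st2)
  # factor subspaces (projectors) unchanged; fit unchanged
  for (k in 2:3) {
    p0 <- tcrossprod(m0$factors[[k]])
    p1 <- tcrossprod(m1$factors[[k]])
    expect_lt(max(abs(p0 - p1)), 1e-8)
  }
  expect_lt(abs(m1$fit - m0$fit), 1e-8)
})

test_that("a zero slice appends a zero mode-1 core row", {
  set.seed(10)
  x <- array(rnorm(4 * 5 * 3), c(4, 5, 3))
  st <- tucker_stream(c(5, 3), c(10, 3, 2))
  for (i in 1:4) st <- tucker_update(st, x[i, , ])
  st <- tucker_update(st, array(0, c(5, 3)))
  m <- tucker_stream_model(st)
  expect_equal(dim(m$core)[1], 5)
  expect_lt(max(abs(m$core[5, , ])), 1e-10)
  expect_error(tucker_update(st, array(0, c(4, 3))), "conform")
})
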