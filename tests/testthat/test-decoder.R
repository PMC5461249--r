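# synthetic feature generator: informative features live in a few
# correlated clusters, the rest is noise
planted_features <- function(n = 120, n_noise = 40, snr_db = 10, seed = 1) {
  set.seed(seed)
  y <- rep(c(TRUE, FALSE), length.out = n)[sample(n)]
  sig <- as.numeric(y)
  amp <- sqrt(10^(snr_db / 10))
  inf1 <- sapply(1:4, function(i) amp * sig + rnorm(n))
  inf2 <- sapply(1:4, function(i) -amp * sig + rnorm(n))
  noise <- matrix(rnorm(n * n_noise), n)
  list(X = cbind(inf1, inf2, noise), y = y, informative = 1:8)
}

test_that("RCE keeps planted informative clusters", {
  hits <- vapply(1:10, function(s) {
    pf <- planted_features(seed = s)
    sel <- rce_select(pf$X, pf$y, n_clusters = 10, elimination_fraction = 0.2,
                      seed = s)
    # both informative clusters survive
    any(sel %in% 1:4) && any(sel %in% 5:8)
  }, TRUE)
  expect_gte(mean(hits), 0.9)
})

test_that("RCE degenerate settings behave as documented", {
  pf <- planted_features(seed = 3)
  expect_equal(rce_select(pf$X, pf$y, elimination_fraction = 0),
               seq_len(ncol(pf$X)))
  # all-noise features: completes and returns a non-empty subset
  set.seed(4)
  sel <- rce_select(matrix(rnorm(60 * 20), 60), rep(c(TRUE, FALSE), 30),
                    n_clusters = 5, seed = 1)
  expect_gt(length(sel), 0)
  expect_error(rce_select(pf$X, rep(TRUE, nrow(pf$X))), "two classes")
})

test_that("the MVPA decoder separates separable classes and calibrates", {
  set.seed(5)
  n <- 80
  y <- rep(c(TRUE, FALSE), each = n / 2)
  X <- cbind(ifelse(y, 3, -3) + 0.1 * rnorm(n), matrix(rnorm(n * 3), n))
  m <- train_mvpa(X, y, config = list(rce = FALSE))
  expect_true(m$informative)
  expect_equal(mean((decoder_score(m, X) > 0) == y), 1)
})

test_that("label-shuffled features give chance accuracy and abstention", {
  accs <- vapply(1:6, function(s) {
    pf <- planted_features(seed = 50 + s)
    ysh <- sample(pf$y)
    folds <- make_folds(length(ysh), 4, seed = s)
    oof <- logical(length(ysh))
    for (f in 1:4) {
      tr <- folds != f
      m <- train_mvpa(pf$X[tr, ], ysh[tr], config = list(rce = FALSE, seed = s))
      oof[!tr] <- decoder_score(m, pf$X[!tr, ]) > 0
    }
    mean(oof == ysh)
  }, 0)
  # binomial CI of 0.5 over 6 x 120 pooled trials
  expect_gt(mean(accs), 0.5 - 2 * sqrt(0.25 / (6 * 120)) - 0.05)
  expect_lt(mean(accs), 0.5 + 2 * sqrt(0.25 / (6 * 120)) + 0.05)
})

test_that("planted P300-like features decode well at 10 dB", {
  accs <- vapply(1:10, function(s) {
    pf <- planted_features(snr_db = 10, seed = 100 + s)
    folds <- make_folds(length(pf$y), 4, seed = s)
    oof <- logical(length(pf$y))
    for (f in 1:4) {
      tr <- folds != f
      m <- train_mvpa(pf$X[tr, ], pf$y[tr], config = list(seed = s))
      oof[!tr] <- decoder_score(m, pf$X[!tr, ]) > 0
    }
    mean(oof == pf$y)
  }, 0)
  expect_gt(median(accs), 0.7)
})

test_that("training is bit-stable and independent of test-set content", {
  pf <- planted_features(seed = 7)
  tr <- 1:80
  m1 <- train_mvpa(pf$X[tr, ], pf$y[tr], config = list(seed = 1))
  # retraining after the test rows change (here: corrupted copy) must give
  # an identical model -- the training path never sees test data
  pf2 <- pf; pf2$X[-tr, ] <- 0
  m2 <- train_mvpa(pf2$X[tr, ], pf2$y[tr], config = list(seed = 1))
  expect_identical(m1$selected, m2$selected)
  expect_identical(m1$svm$mu, m2$svm$mu)
  expect_identical(m1$calibration_p, m2$calibration_p)
  expect_identical(decoder_score(m1, pf$X[-tr, ]), decoder_score(m2, pf$X[-tr, ]))
})

test_that("letter decisions follow the row/column argmax contract", {
  trials <- generate_paradigm(paradigm_spec(n_blocks = 1, cycles_per_block = 2,
                                            targets = "H"), seed = 2)
  # score 1 exactly on the target's row (1) and column (1) highlights
  tgt <- trials$is_target
  res <- decode_letter(as.numeric(tgt), trials, n_cycles_used = 2)
  expect_equal(res$blocks$symbol, "H")
  expect_equal(res$accuracy, 1)
  # all-equal scores tie-break to row 0 / column 0 -> "A"
  res0 <- decode_letter(rep(0, nrow(trials)), trials)
  expect_equal(res0$blocks$row, 0L)
  expect_equal(res0$blocks$col, 0L)
  expect_equal(res0$blocks$symbol, "A")
  expect_error(decode_letter(as.numeric(tgt), trials, n_cycles_used = 3),
               "n_cycles_used")
  expect_error(decode_letter(as.numeric(tgt)[1:10], trials[1:10, ]),
               "incomplete cycle")
})

test_that("more cycles make noisy letter decoding more accurate", {
  spec <- paradigm_spec(n_blocks = 6, cycles_per_block = 8)
  accs <- sapply(1:20, function(s) {
    trials <- generate_paradigm(spec, seed = s)
    set.seed(1000 + s)
    scores <- as.numeric(trials$is_target) + rnorm(nrow(trials), sd = 2.5)
    vapply(c(1, 2, 4, 8), function(nc)
      decode_letter(scores, trials, n_cycles_used = nc)$accuracy, 0)
  })
  mean_acc <- rowMeans(accs)
  expect_gt(cor(mean_acc, c(1, 2, 4, 8), method = "spearman"), 0)
  expect_gt(mean_acc[4], mean_acc[1])
})

test_that("binomial chance test behaves at the extremes", {
  trials <- generate_paradigm(paradigm_spec(n_blocks = 3, cycles_per_block = 1,
                                            targets = c("A", "B", "C")), seed = 1)
  perfect <- decode_letter(as.numeric(trials$is_target), trials)
  expect_equal(perfect$accuracy, 1)
  expect_lt(accuracy_above_chance_p(perfect), 0.01)
})
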