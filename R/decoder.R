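# MVPA letter decoding for the P300 speller: linear SVM with recursive
# cluster elimination (RCE) feature selection, and row/column/letter
# decisions from per-trial decision scores.

#' Recursive cluster elimination feature selection
#'
#' Features are grouped by correlation clustering (average-linkage
#' hierarchical clustering of 1 - |cor|); each round scores every surviving
#' cluster by the cross-validated accuracy of a linear SVM trained on that
#' cluster alone, eliminates the lowest-scoring fraction, and tracks the
#' cross-validated accuracy of the surviving feature set. The feature set
#' of the best-scoring round is returned.
#'
#' @param features Trials x features matrix.
#' @param labels Two-class factor/logical/numeric labels.
#' @param n_clusters Number of correlation clusters.
#' @param elimination_fraction Fraction of clusters dropped per round
#'   (0 disables elimination and returns all features).
#' @param folds Cross-validation folds for cluster scoring.
#' @param seed Integer seed (fold assignment).
#' @return Integer vector of selected feature column indices.
#' @export
rce_select <- function(features, labels, n_clusters = 20,
                       elimination_fraction = 0.2, folds = 3, seed = 1L) {
  X <- as.matrix(features)
  y <- as.factor(labels)
  if (nlevels(y) < 2) stop("labels must contain two classes")
  p <- ncol(X)
  if (elimination_fraction <= 0) return(seq_len(p))
  n_clusters <- min(n_clusters, p)
  sds <- apply(X, 2, stats::sd)
  live <- which(sds > 0)
  if (length(live) < 2) return(seq_len(p))
  cmat <- suppressWarnings(stats::cor(X[, live, drop = FALSE]))
  cmat[!is.finite(cmat)] <- 0
  hc <- stats::hclust(stats::as.dist(1 - abs(cmat)), method = "average")
  cl <- stats::cutree(hc, k = min(n_clusters, length(live)))
  clusters <- split(live, cl)
  fold_id <- with_seed(seed, sample(rep_len(seq_len(folds), nrow(X))))
  cv_acc <- function(cols) {
    acc <- numeric(folds)
    for (f in seq_len(folds)) {
      tr <- fold_id != f
      if (nlevels(droplevels(y[tr])) < 2) { acc[f] <- 0.5; next }
      fit <- svm_train(X[tr, cols, drop = FALSE], y[tr])
      pred <- svm_score(fit, X[!tr, cols, drop = FALSE]) > 0
      acc[f] <- mean(pred == (y[!tr] == levels(y)[2]))
    }
    mean(acc)
  }
  best_set <- unlist(clusters)
  best_acc <- cv_acc(best_set)
  while (length(clusters) > 2) {
    scores <- vapply(clusters, cv_acc, 0)
    ndrop <- max(1L, floor(length(clusters) * elimination_fraction))
    keep <- order(scores, decreasing = TRUE)[seq_len(length(clusters) - ndrop)]
    clusters <- clusters[sort(keep)]
    set <- unlist(clusters)
    acc <- cv_acc(set)
    if (acc >= best_acc) { best_acc <- acc; best_set <- set }
    else if (acc < best_acc - 0.05) break   # accuracy degraded: stop
  }
  sort(unname(best_set))
}

# thin wrappers around e1071 keeping standardization explicit
svm_train <- function(X, y, cost = 1) {
  mu <- colMeans(X); sg <- apply(X, 2, stats::sd); sg[sg == 0] <- 1
  Xs <- sweep(sweep(X, 2, mu), 2, sg, "/")
  fit <- e1071::svm(Xs, factor(y), kernel = "linear", cost = cost, scale = FALSE)
  list(fit = fit, mu = mu, sg = sg, positive = levels(factor(y))[2])
}

svm_score <- function(model, X) {
  Xs <- sweep(sweep(as.matrix(X), 2, model$mu), 2, model$sg, "/")
  dv <- attr(stats::predict(model$fit, Xs, decision.values = TRUE),
             "decision.values")
  s <- as.numeric(dv[, 1])
  # e1071 names the decision column "A/B" with positive values favoring A;
  # flip so larger score always means the positive (second factor) class
  if (startsWith(colnames(dv)[1], paste0(model$positive, "/"))) s else -s
}

#' Train a target/non-target MVPA decoder
#'
#' Feature standardization, optional RCE selection and the linear SVM are
#' all confined to the training data; the returned model carries the
#' selected feature ids and scaling so new trials can be scored without
#' refitting.
#'
#' After fitting, the decoder is calibrated by internal cross-validation on
#' the training data: out-of-fold decision scores are compared between the
#' two classes (one-sided t-test). If the separation is not significant
#' (`p >= calibration_alpha`), the decoder is marked uninformative and
#' abstains at scoring time (constant zero scores), the behaviour a
#' deployed speller should have when its calibration run shows no target
#' signal. Abstention keeps chance-level controls at genuine letter chance
#' instead of letting an arbitrarily-oriented hyperplane harvest residual
#' feature variance.
#'
#' @param features Trials x features matrix.
#' @param labels Logical (or two-level) target labels.
#' @param config List: `rce` (logical, default TRUE when more than 8
#'   features), `n_clusters`, `elimination_fraction`, `cost`, `seed`,
#'   `calibration_alpha` (default 0.01; set to 1 to disable abstention).
#' @param feature_source Tag recording what the features are
#'   ("fmri", "estimated-fmri", "raw-eeg-erp", "latent-subspace").
#' @return A `decoder_model` (fields: `svm`, `selected`, `informative`,
#'   `calibration_p`, `feature_source`, `config`).
#' @export
train_mvpa <- function(features, labels, config = list(),
                       feature_source = "fmri") {
  X <- as.matrix(features)
  y <- factor(as.logical(labels), levels = c(FALSE, TRUE))
  if (nlevels(droplevels(y)) < 2) stop("labels must contain both classes")
  cfg <- utils::modifyList(list(rce = ncol(X) > 8, n_clusters = 20,
                                elimination_fraction = 0.2, cost = 1,
                                seed = 1L, calibration_alpha = 0.01), config)
  sel <- if (isTRUE(cfg$rce)) {
    rce_select(X, y, cfg$n_clusters, cfg$elimination_fraction, seed = cfg$seed)
  } else seq_len(ncol(X))
  Xs <- X[, sel, drop = FALSE]
  fit <- svm_train(Xs, y, cost = cfg$cost)
  # calibration: out-of-fold scores on the training data only
  fold_id <- with_seed(cfg$seed + 101L, sample(rep_len(1:3, nrow(Xs))))
  oof <- rep(NA_real_, nrow(Xs))
  for (f in 1:3) {
    tr <- fold_id != f
    if (nlevels(droplevels(y[tr])) < 2) next
    m <- svm_train(Xs[tr, , drop = FALSE], y[tr], cost = cfg$cost)
    oof[!tr] <- svm_score(m, Xs[!tr, , drop = FALSE])
  }
  calib_p <- tryCatch(
    stats::t.test(oof[y == "TRUE"], oof[y == "FALSE"],
                  alternative = "greater")$p.value,
    error = function(e) 1)
  if (!is.finite(calib_p)) calib_p <- 1
  structure(list(svm = fit, selected = sel,
                 informative = calib_p < cfg$calibration_alpha,
                 calibration_p = calib_p,
                 feature_source = feature_source, config = cfg),
            class = "decoder_model")
}

#' Score trials with a trained decoder
#'
#' An uninformative (uncalibrated) decoder abstains: it returns constant
#' zero scores, so downstream letter decisions fall to the tie-break.
#'
#' @param model A `decoder_model`.
#' @param features Trials x features matrix (training feature layout).
#' @return Numeric decision scores (larger = more target-like).
#' @export
decoder_score <- function(model, features) {
  features <- as.matrix(features)
  if (!isTRUE(model$informative)) return(rep(0, nrow(features)))
  svm_score(model$svm, features[, model$selected, drop = FALSE])
}

#' Decode the spelled letter from per-trial scores
#'
#' Scores are averaged per highlight index over the first `n_cycles_used`
#' cycles of each block; the predicted row is the argmax over row
#' highlights, the column the argmax over column highlights, and the symbol
#' is read from the row-major 6x6 grid. Ties break to the lowest index.
#'
#' @param scores Per-trial decision scores, aligned with `trials`.
#' @param trials Trial table covering the scored trials.
#' @param n_cycles_used Cycles per block entering the average (>= 1).
#' @return A `decoding_result`: per-block predicted row/column/symbol,
#'   accuracy against `target_symbol`, and the inputs used.
#' @export
decode_letter <- function(scores, trials, n_cycles_used = NULL) {
  stopifnot(length(scores) == nrow(trials))
  g <- speller_grid()
  blocks <- unique(trials$block_index)
  out <- data.frame(block_index = blocks, row = NA_integer_, col = NA_integer_,
                    symbol = NA_character_, target = NA_character_,
                    stringsAsFactors = FALSE)
  for (bi in seq_along(blocks)) {
    tb <- trials$block_index == blocks[bi]
    cyc <- sort(unique(trials$cycle_index[tb]))
    ncu <- n_cycles_used %||% length(cyc)
    if (ncu > length(cyc)) stop("n_cycles_used exceeds the cycles available in a block")
    use_cyc <- cyc[seq_len(ncu)]
    use <- tb & trials$cycle_index %in% use_cyc
    if (!all(vapply(use_cyc, function(cc)
      sum(trials$cycle_index == cc & tb) == 12L, TRUE)))
      stop("incomplete cycle coverage in the scored trials")
    sc <- scores[use]
    ht <- trials$highlight_type[use]; hi <- trials$highlight_index[use]
    rmean <- vapply(0:5, function(k) mean(sc[ht == "row" & hi == k]), 0)
    cmean <- vapply(0:5, function(k) mean(sc[ht == "column" & hi == k]), 0)
    out$row[bi] <- which.max(rmean) - 1L
    out$col[bi] <- which.max(cmean) - 1L
    out$symbol[bi] <- g[out$row[bi] + 1L, out$col[bi] + 1L]
    out$target[bi] <- trials$target_symbol[tb][1]
  }
  structure(list(blocks = out,
                 accuracy = mean(out$symbol == out$target),
                 n_cycles_used = n_cycles_used, scores = scores),
            class = "decoding_result")
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf("Letter decoding: %d blocks, accuracy %.2f\n",
              nrow(x$blocks), x$accuracy))
  print(x$blocks[, c("block_index", "symbol", "target")], row.names = FALSE)
  invisible(x)
}

#' Binomial test of letter accuracy against speller chance (1/36)
#'
#' @param result A `decoding_result`.
#' @return p-value of `binom.test(correct, blocks, 1/36, "greater")`.
#' @export
accuracy_above_chance_p <- function(result) {
  k <- sum(result$blocks$symbol == result$blocks$target)
  stats::binom.test(k, nrow(result$blocks), p = 1 / 36,
                    alternative = "greater")$p.value
}
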