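# Surrogate-data null distributions, split-half stability distributions,
# and selection of statistically significant HOPLS parameters into a sparse
# linkage model.
#
# The recorded "parameters" of a fit are the entries of the per-component
# core tensors G_r (X side) and D_r (Y side), scaled by 1/sqrt(n_trials)
# so fits on halves of different sizes are comparable. Components across
# fits are aligned to a reference fit by maximal absolute correlation of
# their full-data latent scores, with signs fixed accordingly; loading
# rotations are pinned by the deterministic sign convention of the
# multilinear SVD.

# parameter vector of a hopls fit: concatenated core entries, 1/sqrt(n) scaled
hopls_param_vector <- function(model, n_trials) {
  v <- unlist(c(lapply(model$G, as.numeric), lapply(model$D, as.numeric)))
  v / sqrt(n_trials)
}

# length/layout of the parameter vector for given ranks
hopls_param_length <- function(R, L, K) R * (prod(L) + prod(K))

# scores of all trials under a fit (sequential X-side projection)
hopls_scores_all <- function(model, X) {
  Xa <- as_tensor_array(X)
  nX <- length(dim(Xa))
  E <- Xa
  Tm <- matrix(0, dim(Xa)[1], model$R)
  for (r in seq_len(model$R)) {
    Z <- ttml(E, lapply(model$P[[r]], t), 2:nX)
    gv <- as.numeric(model$G[[r]])
    g2 <- sum(gv^2)
    tvec <- if (g2 > 1e-300) (unfold(Z, 1) %*% gv) / g2 else matrix(0, dim(Xa)[1], 1)
    E <- E - ttml(model$G[[r]], c(list(tvec), model$P[[r]]), c(1, 2:nX))
    Tm[, r] <- tvec
  }
  Tm
}

# align the components of `model` to `ref` by maximal |correlation| of
# full-data scores; returns the parameter vector with components reordered
# and signs flipped to match the reference
align_params <- function(model, ref, X, n_trials) {
  if (model$R != ref$R) return(hopls_param_vector(model, n_trials))
  Sm <- hopls_scores_all(model, X)
  Sr <- hopls_scores_all(ref, X)
  cc <- suppressWarnings(stats::cor(Sm, Sr))
  cc[!is.finite(cc)] <- 0
  perm <- integer(model$R); sgn <- numeric(model$R)
  avail <- rep(TRUE, model$R)
  for (r in seq_len(model$R)) {
    j <- which.max(ifelse(avail, abs(cc[, r]), -Inf))
    perm[r] <- j; sgn[r] <- sign(cc[j, r] + 1e-300); avail[j] <- FALSE
  }
  Gs <- lapply(seq_len(model$R), function(r) sgn[r] * as.numeric(model$G[[perm[r]]]))
  Ds <- lapply(seq_len(model$R), function(r) sgn[r] * as.numeric(model$D[[perm[r]]]))
  unlist(c(Gs, Ds)) / sqrt(n_trials)
}

#' HOPLS fit specification for resampling procedures
#'
#' @param R,L,K Ranks passed to [hopls_fit()].
#' @param n_splits Split-half fits aggregated (by median) into the test
#'   statistic, both for the observed data and within each surrogate.
#' @export
fit_spec <- function(R = 2, L = c(2, 2), K = c(2, 2), n_splits = 5) {
  structure(list(R = R, L = L, K = K, n_splits = as.integer(n_splits)),
            class = "hopls_fit_spec")
}

#' Time-shuffling surrogate of the predictor tensor
#'
#' Destroys the time-locked predictability from X to Y while preserving
#' within-trial marginals: under the default `"within_trial"` scheme the
#' time axis of X is permuted with one random permutation per trial, shared
#' across channels and frequencies, so the multiset of values per
#' (trial, channel, frequency) fiber is preserved exactly. The
#' `"across_trial"` scheme additionally permutes the trial assignment of
#' the time-shuffled trials, destroying trial-level (aggregate-power)
#' predictability as well; use it when the linkage of interest may be
#' carried by shuffle-invariant within-trial aggregates.
#'
#' @param X Predictor `tfr_tensor` or 4-way array (trial, space, time, freq).
#' @param Y Response tensor (returned untouched).
#' @param seed Integer seed; identical seeds give identical surrogates.
#' @param scheme `"within_trial"` (default) or `"across_trial"`.
#' @return List with `X` (surrogate) and `Y` (unchanged).
#' @export
make_surrogate <- function(X, Y, seed = 1L, scheme = c("within_trial", "across_trial")) {
  scheme <- match.arg(scheme)
  Xa <- as_tensor_array(X)
  d <- dim(Xa)
  if (!length(d) %in% c(3, 4)) stop("X must be a (trial, space, time[, freq]) tensor")
  nt <- d[1]; n_time <- d[3]
  Xs <- with_seed(seed, {
    out <- Xa
    for (i in seq_len(nt)) {
      perm <- sample(n_time)
      if (length(d) == 4) out[i, , , ] <- Xa[i, , perm, , drop = FALSE]
      else out[i, , ] <- Xa[i, , perm, drop = FALSE]
    }
    if (scheme == "across_trial") {
      out <- index_mode1(out, sample(nt))
    }
    out
  })
  if (inherits(X, "tfr_tensor")) {
    X$data <- Xs
    Xs <- X
  }
  list(X = Xs, Y = Y)
}

#' Split-half distribution of HOPLS parameters
#'
#' Fits the model on random halves of the trials and records the aligned
#' parameter vector of each fit plus its prediction R-squared on the
#' complementary half. The first split (all fits with `n_splits = 1`) is
#' the alignment reference.
#'
#' @param X,Y Tensors sharing mode 1 (>= 20 trials unless `n_splits == 1`).
#' @param n_splits Number of random half-splits.
#' @param spec A [fit_spec()].
#' @param seed Integer seed.
#' @return List with `params` (n_splits x n_parameters matrix), `test_r2`
#'   (per split), and the reference fit.
#' @export
split_half_distribution <- function(X, Y, n_splits, spec, seed = 1L) {
  Xa <- as_tensor_array(X); Ya <- as_tensor_array(Y)
  n <- dim(Xa)[1]
  if (n < 20 && n_splits > 1) stop("at least 20 trials required for split-half fits")
  ref <- hopls_fit(Xa, Ya, spec$R, spec$L, spec$K)
  npar <- hopls_param_length(ref$R, spec$L, spec$K)
  params <- matrix(NA_real_, n_splits, npar)
  r2 <- numeric(n_splits)
  if (n_splits == 1) {
    params[1, ] <- hopls_param_vector(ref, n)
    r2[1] <- NA_real_
    return(list(params = params, test_r2 = r2, reference = ref))
  }
  seeds <- with_seed(seed, sample.int(.Machine$integer.max, n_splits))
  for (s in seq_len(n_splits)) {
    half <- with_seed(seeds[s], sample(n, floor(n / 2)))
    m <- hopls_fit(index_mode1(Xa, half), index_mode1(Ya, half),
                   spec$R, spec$L, spec$K)
    params[s, ] <- align_params(m, ref, Xa, length(half))
    r2[s] <- hopls_r2(m, index_mode1(Xa, -half), index_mode1(Ya, -half))
  }
  list(params = params, test_r2 = r2, reference = ref)
}

#' Surrogate null distribution of HOPLS parameters
#'
#' For each surrogate, the predictor tensor is time-shuffled and the model
#' is refitted; the recorded null statistic mirrors the observed one (the
#' median parameter vector over `spec$n_splits` split-half fits), so the
#' observed statistic and the null samples are exchangeable when X and Y
#' are genuinely unlinked.
#'
#' @param X,Y Tensors sharing mode 1.
#' @param n_surrogates Number of surrogates (>= 50 for testing; the
#'   framework default, matching the intended full-scale analysis, is
#'   10000).
#' @param spec A [fit_spec()].
#' @param seed Integer seed; the null is bit-reproducible given the seed.
#' @param scheme Shuffle scheme, see [make_surrogate()].
#' @return A `surrogate_null`: list with `parameter_samples`
#'   (n_surrogates x n_parameters), `n_surrogates`, `seed`, `shuffle_scheme`.
#' @export
null_distribution <- function(X, Y, n_surrogates = 10000, spec = fit_spec(),
                              seed = 1L, scheme = "within_trial") {
  Xa <- as_tensor_array(X); Ya <- as_tensor_array(Y)
  n <- dim(Xa)[1]
  seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1, n_surrogates))
  npar <- hopls_param_length(spec$R, spec$L, spec$K)
  samples <- matrix(NA_real_, n_surrogates, npar)
  for (j in seq_len(n_surrogates)) {
    surr <- make_surrogate(Xa, Ya, seed = seeds[j], scheme = scheme)
    sh <- split_half_distribution(surr$X, surr$Y, spec$n_splits, spec,
                                  seed = seeds[j])
    samples[j, ] <- apply(sh$params, 2, stats::median)
  }
  structure(list(parameter_samples = samples,
                 n_surrogates = as.integer(n_surrogates),
                 seed = as.integer(seed), shuffle_scheme = scheme),
            class = "surrogate_null")
}

#' Select significant HOPLS parameters into a sparse model
#'
#' Per parameter, the observed statistic (median over the split-half fits)
#' is compared with the surrogate null by a two-sided empirical p-value
#' (with the +1 finite-sample correction); Benjamini-Hochberg FDR
#' correction is applied across parameters at level `alpha`, and
#' non-surviving core-tensor entries are set exactly to zero in the
#' effective model.
#'
#' @param observed Output of [split_half_distribution()].
#' @param null A `surrogate_null` over the same parameter layout.
#' @param alpha Significance level (FDR).
#' @return A `sparse_hopls`: list with `base` (the reference fit),
#'   `effective` (core entries zeroed), `significance_mask`, `p_values`
#'   (raw), `p_adjusted`, `alpha`, `correction = "BH"`.
#' @export
sparsify <- function(observed, null, alpha = 0.05) {
  stopifnot(inherits(null, "surrogate_null"))
  obs <- apply(observed$params, 2, stats::median)
  ns <- null$parameter_samples
  if (ncol(ns) != length(obs)) stop("observed and null cover different parameter sets")
  nsur <- nrow(ns)
  p <- vapply(seq_along(obs), function(j) {
    lo <- (1 + sum(ns[, j] <= obs[j])) / (nsur + 1)
    hi <- (1 + sum(ns[, j] >= obs[j])) / (nsur + 1)
    min(1, 2 * min(lo, hi))
  }, 0)
  padj <- stats::p.adjust(p, method = "BH")
  mask <- padj <= alpha & alpha > 0
  base <- observed$reference
  eff <- base
  # scatter the mask back onto the per-component cores (same layout as
  # hopls_param_vector: all G blocks, then all D blocks)
  off <- 0L
  for (r in seq_len(base$R)) {
    len <- length(base$G[[r]])
    keep <- mask[off + seq_len(len)]
    eff$G[[r]][!keep] <- 0
    off <- off + len
  }
  for (r in seq_len(base$R)) {
    len <- length(base$D[[r]])
    keep <- mask[off + seq_len(len)]
    eff$D[[r]][!keep] <- 0
    off <- off + len
  }
  structure(list(base = base, effective = eff, significance_mask = mask,
                 p_values = p, p_adjusted = padj, alpha = alpha,
                 correction = "BH"),
            class = "sparse_hopls")
}

#' Wrap a HOPLS model as an all-significant sparse model
#'
#' Convenience for pipelines that expect a `sparse_hopls` but should use
#' the full (non-sparsified) model.
#'
#' @param model A `hopls_model`.
#' @export
as_sparse_hopls <- function(model) {
  stopifnot(inherits(model, "hopls_model"))
  npar <- sum(vapply(model$G, length, 1L)) + sum(vapply(model$D, length, 1L))
  structure(list(base = model, effective = model,
                 significance_mask = rep(TRUE, npar),
                 p_values = rep(0, npar), p_adjusted = rep(0, npar),
                 alpha = 1, correction = "none"),
            class = "sparse_hopls")
}
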