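# Orchestration of the full analysis: deconvolve the session's BOLD,
# tensorize both modalities, fit the (sparse) HOPLS linkage, derive
# fMRI-like features from EEG, and run the two BCI modes (post-hoc
# simultaneous decoding and the EEG-only run).

#' Default pipeline configuration
#'
#' @param eeg_window,fmri_window Epoch windows (s relative to highlight
#'   onset). The EEG window covers the P300 latency range; the fMRI window
#'   covers the hemodynamically relevant span.
#' @param eeg_freqs,fmri_freqs Morlet frequency grids (Hz).
#' @param eeg_n_cycles,fmri_n_cycles Morlet widths.
#' @param eeg_decim,fmri_decim TFR time-axis decimation factors.
#' @param R,L,K HOPLS ranks.
#' @param upsample_factor Deconvolution upsampling (TR 0.2 s data is
#'   already at the effective resolution of interest, so 1 by default).
#' @param bold_feature_window Window (s) whose mean convolved response
#'   forms the per-voxel feature.
#' @param subspace_ranks Tucker ranks (space, time, freq) for the
#'   latent-subspace feature family.
#' @param folds Cross-validation folds.
#' @param seed Integer seed.
#' @export
pipeline_config <- function(eeg_window = c(0, 1), fmri_window = c(0, 8),
                            eeg_freqs = default_freqs("eeg"),
                            fmri_freqs = default_freqs("fmri"),
                            eeg_n_cycles = 7, fmri_n_cycles = 3,
                            eeg_decim = 25L, fmri_decim = 4L,
                            R = 5, L = c(3, 3, 3), K = c(3, 3, 3),
                            upsample_factor = 1L,
                            bold_feature_window = c(2, 6),
                            subspace_ranks = c(3, 3, 3),
                            folds = 5, seed = 1L) {
  as.list(environment())
}

#' Deconvolve a session's BOLD and assemble the paired TFR tensors
#'
#' Runs [blind_deconvolve()] per voxel (exogenous input = the highlight
#' boxcar from the trial table), epochs both modalities around trial
#' onsets, and builds the z-scored log-power tensors. The trial axes of the
#' two tensors are identical by construction, which the HOPLS coupling
#' requires and this function asserts.
#'
#' @param session A `speller_session`.
#' @param config A [pipeline_config()].
#' @return List with `X` (EEG tensor), `Y` (deconvolved-fMRI tensor),
#'   `eeg_norm`/`fmri_norm` (z-scoring references for streaming),
#'   `vox_params` (estimated Balloon parameters), `hrf_dt`, `hrf_kernels`
#'   (per voxel, at the Y tensor's time step), `neuronal` (per-voxel
#'   deconvolved series), and `trials`.
#' @export
session_tensors <- function(session, config = pipeline_config()) {
  stopifnot(inherits(session, "speller_session"))
  cfg <- config
  trials <- session$trials
  TR <- session$TR
  nvox <- length(session$bold)
  # deconvolve only the span the epochs need (plus settle-out margin)
  n_need <- ceiling((max(trials$onset) + cfg$fmri_window[2] + 10) / TR)
  n_bold <- min(length(session$bold[[1]]$values), n_need)
  session$bold <- lapply(session$bold, function(b) {
    b$values <- b$values[seq_len(n_bold)]; b
  })
  tgrid <- (seq_len(n_bold)) * TR
  boxcar <- vapply(tgrid, function(tt)
    as.numeric(any(trials$onset <= tt & tt < trials$onset + trials$duration)), 0)
  neuronal <- vector("list", nvox)
  vox_params <- vector("list", nvox)
  for (v in seq_len(nvox)) {
    dec <- blind_deconvolve(session$bold[[v]],
                            upsample_factor = cfg$upsample_factor,
                            exogenous_input = boxcar)
    neuronal[[v]] <- dec$neuronal
    vox_params[[v]] <- dec$params
  }
  dt_n <- neuronal[[1]]$dt
  nmat <- do.call(rbind, lapply(neuronal, function(x) x$values))
  rownames(nmat) <- vapply(session$bold, function(b) b$space_id, "")
  ep_eeg <- epoch(session$eeg, trials, cfg$eeg_window)
  ep_fmri <- epoch(nmat, trials, cfg$fmri_window, fs = 1 / dt_n)
  eeg_norm <- tensor_norm_stats(ep_eeg, cfg$eeg_freqs, cfg$eeg_n_cycles,
                                cfg$eeg_decim, modality = "eeg")
  fmri_norm <- tensor_norm_stats(ep_fmri, cfg$fmri_freqs, cfg$fmri_n_cycles,
                                 cfg$fmri_decim, modality = "fmri")
  X <- build_tensor_with_ref(ep_eeg, eeg_norm)
  Y <- build_tensor_with_ref(ep_fmri, fmri_norm)
  stopifnot(dim(X$data)[1] == dim(Y$data)[1])
  hrf_dt <- dt_n * cfg$fmri_decim
  # integrate each kernel on a fine grid (stable for short transit times),
  # then decimate to the Y tensor's time step
  sub <- ceiling(hrf_dt / 0.1)
  dt_k <- hrf_dt / sub
  hrf_kernels <- lapply(vox_params, function(p) {
    kf <- hrf_impulse_response(p, dt = dt_k, duration = max(20, hrf_dt * 2))
    kf[seq(sub, length(kf), by = sub)]
  })
  list(X = X, Y = Y, eeg_norm = eeg_norm, fmri_norm = fmri_norm,
       vox_params = vox_params, hrf_dt = hrf_dt, hrf_kernels = hrf_kernels,
       neuronal = neuronal, trials = trials, config = cfg)
}

#' Fit the EEG-to-fMRI linkage for a session
#'
#' Convenience wrapper: [session_tensors()] then [hopls_fit()], optionally
#' followed by surrogate-based sparsification.
#'
#' @param session A `speller_session`.
#' @param config A [pipeline_config()].
#' @param sparsify_spec Optional list with `n_surrogates`, `n_splits`,
#'   `alpha`; `NULL` (default) wraps the full model via [as_sparse_hopls()].
#' @param surrogate_train If `TRUE`, the linkage (and everything trained
#'   downstream of the returned tensors) is built on a time-shuffled
#'   surrogate of the EEG tensor (an `"across_trial"` shuffle), yielding a
#'   null-trained chain for control analyses.
#' @param tensors Optional precomputed [session_tensors()] output, to avoid
#'   re-deconvolving when fitting several linkages on one session.
#' @return List: `linkage` (a `sparse_hopls`), plus everything from
#'   [session_tensors()].
#' @export
fit_linkage <- function(session, config = pipeline_config(),
                        sparsify_spec = NULL, surrogate_train = FALSE,
                        tensors = NULL) {
  st <- tensors %||% session_tensors(session, config)
  Xa <- st$X; Ya <- st$Y
  if (surrogate_train) {
    s <- make_surrogate(Xa, Ya, seed = config$seed + 77L, scheme = "across_trial")
    Xa <- s$X
    # the whole chain is null-trained: downstream feature extraction and
    # decoder training must also see the surrogate predictor tensor
    st$X <- Xa
  }
  dX <- dim(as_tensor_array(Xa)); dY <- dim(as_tensor_array(Ya))
  L <- pmin(config$L, dX[-1]); K <- pmin(config$K, dY[-1])
  if (is.null(sparsify_spec)) {
    linkage <- as_sparse_hopls(hopls_fit(Xa, Ya, config$R, L, K))
  } else {
    sp <- fit_spec(R = config$R, L = L, K = K,
                   n_splits = sparsify_spec$n_splits %||% 5)
    obs <- split_half_distribution(Xa, Ya, sp$n_splits, sp, seed = config$seed)
    nl <- null_distribution(Xa, Ya, sparsify_spec$n_surrogates %||% 200, sp,
                            seed = config$seed + 1L)
    linkage <- sparsify(obs, nl, sparsify_spec$alpha %||% 0.05)
  }
  c(list(linkage = linkage), st)
}

# collapse a predicted Y tensor (trials x voxel x time x freq, z-log-power
# units) to per-trial per-voxel BOLD-like features: average over frequency,
# convolve each voxel's time course with its HRF kernel, average the
# response over the feature window.
estimated_fmri_features <- function(Ypred, fit, config) {
  d <- dim(Ypred)
  nt <- d[1]; nvox <- d[2]
  tv <- seq_len(d[3]) * fit$hrf_dt
  win <- config$bold_feature_window
  use <- tv >= win[1] & tv <= win[2]
  if (!any(use)) use <- rep(TRUE, d[3])
  feats <- matrix(0, nt, nvox)
  for (v in seq_len(nvox)) {
    k <- fit$hrf_kernels[[v]]
    for (i in seq_len(nt)) {
      tc <- rowMeans(matrix(Ypred[i, v, , ], d[3]))
      conv <- convolve_with_hrf(neuronal_ts(tc, fit$hrf_dt), k, fit$hrf_dt)
      feats[i, v] <- mean(conv$values[use])
    }
  }
  feats
}

# family (a): epoch the measured BOLD and average the feature window
bold_mvpa_features <- function(session, config) {
  bmat <- do.call(rbind, lapply(session$bold, function(b) b$values))
  ep <- epoch(bmat, session$trials, config$fmri_window, fs = 1 / session$TR)
  win <- config$bold_feature_window
  use <- ep$times >= win[1] & ep$times <= win[2]
  apply(ep$data[, , use, drop = FALSE], c(1, 2), mean)
}

# family (e): ERP amplitude (mean 0.25-0.45 s) and peak latency per channel
erp_features <- function(session, config) {
  ep <- epoch(session$eeg, session$trials, config$eeg_window)
  use <- ep$times >= 0.25 & ep$times <= 0.45
  nt <- dim(ep$data)[1]; nch <- dim(ep$data)[2]
  out <- matrix(0, nt, 2 * nch)
  for (i in seq_len(nt)) {
    seg <- matrix(ep$data[i, , ], nch)
    amp <- rowMeans(seg[, use, drop = FALSE])
    lat <- apply(seg, 1, function(x) ep$times[which.max(x)])
    out[i, ] <- c(amp, lat)
  }
  out
}

# family (d): per-trial Tucker core of the EEG tensor (modes 2..4 projected)
latent_subspace_features <- function(X, config) {
  Xa <- as_tensor_array(X)
  d <- dim(Xa)
  rk <- pmin(config$subspace_ranks, d[-1])
  tm <- tucker_decompose(Xa, c(d[1], rk))
  core_per_trial <- ttml(Xa, lapply(tm$factors[-1], t), 2:4)
  matrix(unfold(core_per_trial, 1), d[1])
}

#' Post-hoc letter decoding of a simultaneous session
#'
#' Decodes the spelled letters from the feature families of the framework:
#' (a) measured fMRI MVPA, (b) estimated fMRI via the sparse HOPLS
#' prediction re-convolved with the voxel HRFs, (c) the full (non-sparse)
#' HOPLS estimate, (d) latent-subspace (Tucker core) EEG features, and
#' (e) ERP amplitude/latency features. All families share identical
#' cross-validation folds; every trial is scored out-of-fold and letters
#' are decoded from the out-of-fold scores.
#'
#' @param session A `speller_session` (both modalities present).
#' @param fit Output of [fit_linkage()] on this session.
#' @param config The [pipeline_config()] used for the fit.
#' @param families Subset of `c("fmri", "estimated", "full", "subspace",
#'   "erp")`.
#' @param n_cycles_used Cycles per block entering the letter decision.
#' @param permute_trials Chance-level control: permute the feature rows
#'   relative to the trial table (one seeded permutation), destroying both
#'   the label correspondence seen by the SVM and the highlight alignment
#'   used for the letter decision.
#' @return A list of `decoding_result` objects, one per family, each with
#'   an added `cv_auc_proxy` (out-of-fold target/non-target accuracy).
#' @export
run_posthoc_decoding <- function(session, fit, config = fit$config,
                                 families = c("fmri", "estimated", "full",
                                              "subspace", "erp"),
                                 n_cycles_used = NULL,
                                 permute_trials = FALSE) {
  stopifnot(inherits(session, "speller_session"))
  if (is.null(session$bold)) stop("post-hoc decoding requires both modalities")
  trials <- session$trials
  y <- trials$is_target
  perm <- if (permute_trials)
    with_seed(config$seed + 31L, sample(nrow(trials))) else seq_len(nrow(trials))
  featsets <- list()
  if ("fmri" %in% families)
    featsets$fmri <- bold_mvpa_features(session, config)
  if ("estimated" %in% families)
    featsets$estimated <- estimated_fmri_features(
      hopls_predict(fit$linkage, fit$X), fit, config)
  if ("full" %in% families)
    featsets$full <- estimated_fmri_features(
      hopls_predict(fit$linkage$base, fit$X), fit, config)
  if ("subspace" %in% families)
    featsets$subspace <- latent_subspace_features(fit$X, config)
  if ("erp" %in% families)
    featsets$erp <- erp_features(session, config)
  n <- nrow(trials)
  fold_id <- with_seed(config$seed, sample(rep_len(seq_len(config$folds), n)))
  out <- list()
  for (fam in names(featsets)) {
    Xf <- featsets[[fam]][perm, , drop = FALSE]
    if (all(abs(Xf) < 1e-12)) {
      scores <- rep(0, n)
      acc <- 0.5
    } else {
      scores <- numeric(n)
      accs <- numeric(config$folds)
      for (f in seq_len(config$folds)) {
        tr <- fold_id != f
        dm <- train_mvpa(Xf[tr, , drop = FALSE], y[tr],
                         config = list(seed = config$seed),
                         feature_source = fam)
        scores[!tr] <- decoder_score(dm, Xf[!tr, , drop = FALSE])
        accs[f] <- mean((scores[!tr] > 0) == y[!tr])
      }
      acc <- mean(accs)
    }
    res <- decode_letter(scores, trials, n_cycles_used)
    res$cv_auc_proxy <- acc
    res$feature_source <- fam
    out[[fam]] <- res
  }
  out
}

#' EEG-only BCI run driven by estimated fMRI-like features
#'
#' Streams the trials of an EEG-only recording through the trained chain:
#' per trial, the EEG epoch is tensorized with the training normalization,
#' appended to a sequential Tucker stream (the near-real-time update path),
#' pushed through the HOPLS forward prediction, re-convolved with the
#' voxel-specific HRFs, and scored by the trained decoder. Per-stage
#' latencies are logged.
#'
#' @param eeg An [eeg_recording()] (EEG-only run).
#' @param trials Trial table of the run.
#' @param fit Output of [fit_linkage()] from the prior simultaneous
#'   session.
#' @param decoder A `decoder_model` trained on estimated-fMRI features of
#'   the simultaneous session.
#' @param config The [pipeline_config()] used for training.
#' @param n_cycles_used Cycles per block entering the letter decision.
#' @return A `decoding_result` with an added `latency_log` (per-trial
#'   stage timings, s) and `scores`.
#' @export
run_eeg_only_bci <- function(eeg, trials, fit, decoder,
                             config = fit$config, n_cycles_used = NULL) {
  stopifnot(inherits(eeg, "eeg_recording"))
  if (!identical(dim(fit$eeg_norm$mu)[1], nrow(eeg$samples)))
    stop("EEG channel count does not match the trained linkage")
  n <- nrow(trials)
  scores <- numeric(n)
  lat <- matrix(0, n, 4, dimnames = list(NULL, c("tfr", "tucker", "predict", "score")))
  dX <- dim(as_tensor_array(fit$X))
  stream <- tucker_stream(dX[-1], c(n, pmin(config$subspace_ranks, dX[-1])))
  for (i in seq_len(n)) {
    t0 <- proc.time()[3]
    ep <- epoch(eeg, trials[i, , drop = FALSE], config$eeg_window)
    xt <- build_tensor_with_ref(ep, fit$eeg_norm)
    t1 <- proc.time()[3]
    stream <- tucker_update(stream, xt$data[1, , , ])
    t2 <- proc.time()[3]
    yp <- hopls_predict(fit$linkage, xt$data)
    t3 <- proc.time()[3]
    feats <- estimated_fmri_features(yp, fit, config)
    scores[i] <- decoder_score(decoder, feats)
    t4 <- proc.time()[3]
    lat[i, ] <- c(t1 - t0, t2 - t1, t3 - t2, t4 - t3)
  }
  res <- decode_letter(scores, trials, n_cycles_used)
  res$latency_log <- lat
  res$tucker_stream <- stream
  res
}

#' Train the estimated-fMRI decoder for the EEG-only mode
#'
#' @param fit Output of [fit_linkage()] (simultaneous session).
#' @param config The matching [pipeline_config()].
#' @return A `decoder_model` over estimated-fMRI features.
#' @export
train_bci_decoder <- function(fit, config = fit$config) {
  feats <- estimated_fmri_features(hopls_predict(fit$linkage, fit$X), fit, config)
  if (all(abs(feats) < 1e-12)) {
    # degenerate (e.g. fully sparsified) linkage: constant features carry no
    # information; train on a tiny jitter so the SVM is well-defined
    feats <- feats + with_seed(config$seed, matrix(stats::rnorm(length(feats), sd = 1e-6),
                                                   nrow(feats)))
  }
  train_mvpa(feats, fit$trials$is_target, config = list(seed = config$seed),
             feature_source = "estimated-fmri")
}

#' Restrict a session to a subset of blocks
#'
#' The recordings are kept whole (epoching handles alignment); only the
#' trial table is restricted.
#'
#' @param session A `speller_session`.
#' @param blocks Block indices to keep.
#' @export
subset_session <- function(session, blocks) {
  session$trials <- session$trials[session$trials$block_index %in% blocks, ,
                                   drop = FALSE]
  session
}

#' Deterministic fold assignment
#'
#' Splits `n` units into `K` folds (seeded). With `K == n` every fold is a
#' singleton, so K-fold and leave-one-out coincide exactly.
#'
#' @param n Number of units.
#' @param K Number of folds.
#' @param seed Integer seed.
#' @return Integer fold id per unit.
#' @export
make_folds <- function(n, K, seed = 1L) {
  if (K > n) stop("K cannot exceed n")
  with_seed(seed, sample(rep_len(seq_len(K), n)))
}

#' Cross-subject generalization of the BCI chain
#'
#' For each synthetic subject, the letters of held-out blocks are decoded
#' with a linkage + decoder trained (i) on the subject's own training
#' blocks ("within"), (ii) on all other subjects pooled ("pooled_prior"),
#' and (iii) on one random other subject ("random_prior"). Block-level
#' K-fold and leave-one-block-out accuracies are reported, and when
#' covariates are supplied the within-vs-transfer accuracy difference is
#' regressed on covariate mismatch (descriptively).
#'
#' @param sessions List of >= 3 `speller_session` objects (one per
#'   subject; distinct seeds/mixing matrices).
#' @param pairing_covariates Optional data frame (one row per subject) of
#'   numeric covariates.
#' @param config A [pipeline_config()].
#' @param n_cycles_used Cycles per block for the letter decision.
#' @return List with `accuracy` (subject x mode data frame), `kfold`
#'   (K = n blocks equals leave-one-out by construction; reported per
#'   subject), and `covariate_model` (lm summary or NULL).
#' @export
evaluate_generalization <- function(sessions, pairing_covariates = NULL,
                                    config = pipeline_config(),
                                    n_cycles_used = NULL) {
  ns <- length(sessions)
  if (ns < 3) stop("at least 3 subjects required")
  # per subject: linkage + decoder trained on the first half of the blocks;
  # the remaining blocks are the test set for every transfer mode
  all_blocks <- lapply(sessions, function(s) sort(unique(s$trials$block_index)))
  train_blocks <- lapply(all_blocks, function(b) b[seq_len(max(1, floor(length(b) / 2)))])
  test_blocks <- mapply(setdiff, all_blocks, train_blocks, SIMPLIFY = FALSE)
  if (any(lengths(test_blocks) == 0)) stop("each subject needs at least 2 blocks")
  fits <- lapply(seq_len(ns), function(s)
    fit_linkage(subset_session(sessions[[s]], train_blocks[[s]]), config = config))
  decs <- lapply(fits, train_bci_decoder, config = config)
  acc <- data.frame(subject = seq_len(ns), within = NA_real_,
                    pooled_prior = NA_real_, random_prior = NA_real_)
  rnd <- with_seed(config$seed + 5L,
                   vapply(seq_len(ns), function(s) sample(setdiff(seq_len(ns), s), 1), 1L))
  for (s in seq_len(ns)) {
    ses <- subset_session(sessions[[s]], test_blocks[[s]])
    run_with <- function(fit, dec) {
      r <- run_eeg_only_bci(ses$eeg, ses$trials, fit, dec, config = config,
                            n_cycles_used = n_cycles_used)
      r$accuracy
    }
    acc$within[s] <- run_with(fits[[s]], decs[[s]])
    others <- setdiff(seq_len(ns), s)
    # "pooled_prior" averages the other subjects' trained chains, so the
    # subject column doubles as leave-one-subject-out transfer accuracy
    pool_accs <- vapply(others, function(o) run_with(fits[[o]], decs[[o]]), 0)
    acc$pooled_prior[s] <- mean(pool_accs)
    acc$random_prior[s] <- run_with(fits[[rnd[s]]], decs[[rnd[s]]])
  }
  covariate_model <- NULL
  if (!is.null(pairing_covariates)) {
    mism <- vapply(seq_len(ns), function(s)
      mean(abs(as.numeric(pairing_covariates[rnd[s], ]) -
               as.numeric(pairing_covariates[s, ]))), 0)
    covariate_model <- stats::lm((acc$within - acc$random_prior) ~ mism)
  }
  list(accuracy = acc, random_prior_map = rnd, covariate_model = covariate_model)
}
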