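# Complex Morlet time-frequency representation, trial epoching, and
# assembly of 4-way (trial x space x time x frequency) tensors for both
# modalities. EEG and deconvolved fMRI keep their native sampling rates;
# only the trial axis must agree between the paired tensors.

#' EEG recording container
#'
#' @param samples Channels x time matrix (microvolts).
#' @param fs Sampling rate (Hz).
#' @param channel_names Optional channel labels.
#' @export
eeg_recording <- function(samples, fs, channel_names = NULL) {
  samples <- as.matrix(samples)
  if (!is.numeric(fs) || fs <= 0) stop("fs must be > 0")
  if (nrow(samples) < 1) stop("at least one channel required")
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(nrow(samples)))
  structure(list(samples = samples, fs = fs, channel_names = channel_names),
            class = "eeg_recording")
}

#' Complex Morlet wavelet transform
#'
#' Convolves the signal with complex Morlet wavelets
#' `exp(2i pi f t) exp(-t^2 / (2 sigma_t^2))` with `sigma_t = n_cycles /
#' (2 pi f)`, L1-normalized so a unit-amplitude sinusoid at the bin
#' frequency yields coefficients of magnitude ~0.5. Samples closer to
#' either edge than one wavelet half-length are flagged.
#'
#' @param signal Numeric time series.
#' @param fs Sampling rate (Hz).
#' @param freqs Analysis frequencies (Hz), all below the Nyquist rate.
#' @param n_cycles Wavelet width in cycles (>= 1).
#' @return List with `coef` (complex, time x frequency), `power`
#'   (squared magnitude), `freqs`, and `edge` (logical, time x frequency).
#' @export
morlet_tfr <- function(signal, fs, freqs, n_cycles = 7) {
  if (any(freqs >= fs / 2)) stop("analysis frequencies must be below the Nyquist frequency fs/2")
  if (any(freqs <= 0)) stop("analysis frequencies must be positive")
  if (n_cycles < 1) stop("n_cycles must be >= 1")
  x <- as.numeric(signal)
  n <- length(x)
  coef <- matrix(0i, n, length(freqs))
  edge <- matrix(FALSE, n, length(freqs))
  for (j in seq_along(freqs)) {
    f <- freqs[j]
    sigma_t <- n_cycles / (2 * pi * f)
    half <- max(1L, ceiling(3.5 * sigma_t * fs))
    tt <- seq(-half, half) / fs
    w <- exp(2i * pi * f * tt) * exp(-tt^2 / (2 * sigma_t^2))
    w <- w / sum(abs(w))
    # centered convolution via FFT (padded to an FFT-friendly length)
    nf <- stats::nextn(n + length(w) - 1L, c(2, 3, 5))
    X <- stats::fft(c(x, numeric(nf - n)))
    W <- stats::fft(c(w, numeric(nf - length(w))))
    full <- stats::fft(X * W, inverse = TRUE) / nf
    coef[, j] <- full[half + seq_len(n)]
    ne <- min(half, n)
    edge[seq_len(ne), j] <- TRUE
    edge[n - seq_len(ne) + 1L, j] <- TRUE
  }
  list(coef = coef, power = Mod(coef)^2, freqs = freqs, edge = edge)
}

#' Epoch a recording around trial onsets
#'
#' Cuts per-trial segments aligned to trial onsets: the sample holding the
#' onset (0-based index `round(onset * fs)`) maps to time offset 0, and the
#' window is half-open, `[t_start, t_end)`.
#'
#' @param signal An [eeg_recording()], a [neuronal_ts()], or a plain
#'   space x time matrix with attribute-free rows (then `fs` is required).
#' @param trials A trial table (data frame with an `onset` column, seconds).
#' @param window Numeric `c(t_start, t_end)` in seconds relative to onset.
#' @param fs Sampling rate, only for plain matrices.
#' @return List with `data` (trials x space x time array), `times` (offsets
#'   in seconds), `fs`, and `space` labels.
#' @export
epoch <- function(signal, trials, window, fs = NULL) {
  if (inherits(signal, "eeg_recording")) {
    mat <- signal$samples; fs <- signal$fs; space <- signal$channel_names
  } else if (inherits(signal, "neuronal_ts")) {
    mat <- matrix(signal$values, nrow = 1); fs <- 1 / signal$dt
    space <- signal$space_id
  } else {
    mat <- as.matrix(signal)
    if (is.null(fs)) stop("fs required for plain matrix input")
    space <- rownames(mat) %||% paste0("s", seq_len(nrow(mat)))
  }
  stopifnot(length(window) == 2, window[2] > window[1])
  nsamp <- round((window[2] - window[1]) * fs)
  start0 <- round((trials$onset + window[1]) * fs)   # 0-based
  bad <- which(start0 < 0 | start0 + nsamp > ncol(mat))
  if (length(bad)) {
    stop(sprintf("trial window out of recording bounds for trial(s): %s",
                 paste(bad, collapse = ", ")))
  }
  out <- array(0, c(nrow(trials), nrow(mat), nsamp))
  for (i in seq_len(nrow(trials))) {
    out[i, , ] <- mat[, start0[i] + seq_len(nsamp), drop = FALSE]
  }
  list(data = out, times = window[1] + (seq_len(nsamp) - 1) / fs,
       fs = fs, space = space)
}

#' Assemble a 4-way time-frequency tensor from epoched data
#'
#' Applies [morlet_tfr()] per trial and space channel, stacks the power to a
#' (trial, space, time, frequency) array, log-transforms it and z-scores each
#' (space, time, frequency) bin across trials. Bins with zero variance across
#' trials map to zero, so degenerate inputs never produce NaN.
#'
#' @param epochs Output of [epoch()] (all trials share one window length).
#' @param freqs Analysis frequencies (Hz).
#' @param n_cycles Morlet width in cycles.
#' @param time_decim Keep every `time_decim`-th TFR sample (integer >= 1).
#' @param modality Tag stored on the tensor ("eeg" or "fmri").
#' @param normalize If `FALSE`, keep raw power (no log/z-scoring).
#' @return A `tfr_tensor`: list with `data` (4-way array), axis vectors
#'   `trials`, `space`, `times`, `freqs`, and `modality`.
#' @export
build_tensor <- function(epochs, freqs, n_cycles = 7, time_decim = 1L,
                         modality = "eeg", normalize = TRUE) {
  x <- epochs$data
  d <- dim(x)
  if (length(d) != 3) stop("epochs$data must be a trials x space x time array")
  keep <- seq(1L, d[3], by = as.integer(time_decim))
  out <- array(0, c(d[1], d[2], length(keep), length(freqs)))
  for (i in seq_len(d[1])) {
    for (s in seq_len(d[2])) {
      tf <- morlet_tfr(x[i, s, ], epochs$fs, freqs, n_cycles)
      out[i, s, , ] <- tf$power[keep, , drop = FALSE]
    }
  }
  if (normalize) {
    out <- log(out + 1e-30)
    mu <- apply(out, c(2, 3, 4), mean)
    sg <- apply(out, c(2, 3, 4), stats::sd)
    for (i in seq_len(d[1])) {
      sl <- array(out[i, , , , drop = FALSE], dim(out)[-1])
      z <- (sl - mu) / sg
      z[!is.finite(z)] <- 0
      out[i, , , ] <- z
    }
    if (d[1] == 1) out[] <- 0   # single trial: no across-trial variance
  }
  if (any(!is.finite(out))) stop("tensor assembly produced non-finite values")
  structure(list(data = out, trials = seq_len(d[1]), space = epochs$space,
                 times = epochs$times[keep], freqs = freqs,
                 modality = modality),
            class = "tfr_tensor")
}

#' Apply a stored z-scoring reference to new epochs
#'
#' For streaming single trials the across-trial statistics must come from
#' training data; this builds the raw power tensor and standardizes it with
#' the supplied means/sds.
#'
#' @param epochs Output of [epoch()].
#' @param ref A `tfr_norm` reference from [tensor_norm_stats()].
#' @return A `tfr_tensor` standardized like the training tensor.
#' @export
build_tensor_with_ref <- function(epochs, ref) {
  raw <- build_tensor(epochs, ref$freqs, ref$n_cycles, ref$time_decim,
                      modality = ref$modality, normalize = FALSE)
  out <- log(raw$data + 1e-30)
  for (i in seq_len(dim(out)[1])) {
    sl <- array(out[i, , , , drop = FALSE], dim(out)[-1])
    z <- (sl - ref$mu) / ref$sg
    z[!is.finite(z)] <- 0
    out[i, , , ] <- z
  }
  raw$data <- out
  raw
}

#' Extract z-scoring statistics for streaming use
#'
#' @param epochs Training epochs (output of [epoch()]).
#' @inheritParams build_tensor
#' @return A `tfr_norm` list with per-bin `mu`, `sg` and the TFR settings.
#' @export
tensor_norm_stats <- function(epochs, freqs, n_cycles = 7, time_decim = 1L,
                              modality = "eeg") {
  raw <- build_tensor(epochs, freqs, n_cycles, time_decim,
                      modality = modality, normalize = FALSE)
  lp <- log(raw$data + 1e-30)
  mu <- apply(lp, c(2, 3, 4), mean)
  sg <- apply(lp, c(2, 3, 4), stats::sd)
  structure(list(mu = mu, sg = sg, freqs = freqs, n_cycles = n_cycles,
                 time_decim = as.integer(time_decim), modality = modality),
            class = "tfr_norm")
}

#' Default analysis frequency grids
#'
#' EEG: 2-40 Hz, 20 log-spaced bins (7-cycle wavelets). Deconvolved fMRI at
#' an effective dt of 0.2 s (Nyquist 2.5 Hz): 0.03-2 Hz, 8 log-spaced bins
#' (3-cycle wavelets).
#'
#' @param modality `"eeg"` or `"fmri"`.
#' @param n Number of bins (defaults to the modality's standard count).
#' @export
default_freqs <- function(modality = c("eeg", "fmri"), n = NULL) {
  modality <- match.arg(modality)
  if (modality == "eeg") exp(seq(log(2), log(40), length.out = n %||% 20))
  else exp(seq(log(0.03), log(2), length.out = n %||% 8))
}

#' @export
print.tfr_tensor <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("TFR tensor [%s]: %d trials x %d space x %d time x %d freq\n",
              x$modality, d[1], d[2], d[3], d[4]))
  invisible(x)
}
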