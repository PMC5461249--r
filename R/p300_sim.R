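# Synthetic P300-speller sessions with a planted EEG-fMRI linkage.
#
# The paradigm is the classic 6x6 row/column speller: per displaying cycle
# every row and every column is highlighted once (500 ms) in random order,
# with inter-trial intervals drawn uniformly from 2-5 s. Two latent neural
# sources drive both modalities: an early "visual" source responding to
# every highlight and a "P300" source responding only to target highlights
# at a latency jittered uniformly in 250-400 ms. EEG is a seeded linear
# mixture of the sources plus 1/f noise at 250 Hz; BOLD is the per-voxel
# Balloon-model response to the region-mapped sources at TR 0.2 s plus
# Gaussian noise. The shared trial structure is the planted linkage the
# analysis pipeline is meant to recover.

#' The 6x6 speller grid (A-Z then 0-9, row-major)
#' @export
speller_grid <- function() {
  matrix(c(LETTERS, as.character(0:9)), nrow = 6, ncol = 6, byrow = TRUE)
}

#' P300 speller paradigm specification
#'
#' @param n_blocks Number of trial blocks (each block spells one symbol).
#' @param cycles_per_block Displaying cycles per block (12 trials each).
#' @param highlight_duration Highlight duration (s).
#' @param iti_range Inter-trial interval range (s), drawn uniformly.
#' @param targets Target symbol per block (defaults drawn at random per
#'   session seed).
#' @export
paradigm_spec <- function(n_blocks = 4, cycles_per_block = 12,
                          highlight_duration = 0.5, iti_range = c(2, 5),
                          targets = NULL) {
  if (iti_range[1] >= iti_range[2]) stop("iti_range must be increasing")
  g <- speller_grid()
  if (length(unique(as.vector(g))) != 36) stop("grid symbols must be distinct")
  if (!is.null(targets)) {
    if (length(targets) != n_blocks || !all(targets %in% g))
      stop("targets must name one grid symbol per block")
  }
  structure(list(n_blocks = as.integer(n_blocks),
                 cycles_per_block = as.integer(cycles_per_block),
                 highlight_duration = highlight_duration,
                 iti_range = iti_range, grid = g, targets = targets),
            class = "paradigm_spec")
}

#' Generate the trial table for a speller session
#'
#' Each cycle highlights the 6 rows and 6 columns exactly once in a random
#' order; a trial is a target trial when the highlighted row or column
#' contains the block's target symbol (2 target trials per cycle). Onsets
#' advance by the highlight duration plus a uniform ITI.
#'
#' @param spec A [paradigm_spec()].
#' @param seed Integer seed; the table is deterministic given the seed.
#' @return A `trial_table` data frame with columns `onset`, `duration`,
#'   `highlight_type` ("row"/"column"), `highlight_index` (0-5),
#'   `is_target`, `cycle_index`, `block_index`, `target_symbol`.
#' @export
generate_paradigm <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "paradigm_spec"))
  if (spec$cycles_per_block < 1 || spec$n_blocks < 1) stop("need at least one cycle")
  with_seed(seed, {
    g <- spec$grid
    targets <- spec$targets %||% sample(as.vector(g), spec$n_blocks, replace = TRUE)
    rows <- list()
    t_cursor <- 5  # lead-in before the first highlight
    cyc_global <- 0L
    for (b in seq_len(spec$n_blocks)) {
      tpos <- which(g == targets[b], arr.ind = TRUE)
      for (cyc in seq_len(spec$cycles_per_block)) {
        cyc_global <- cyc_global + 1L
        ord <- sample(12)
        ht <- c(rep("row", 6), rep("column", 6))[ord]
        hi <- c(0:5, 0:5)[ord]
        for (k in 1:12) {
          is_tgt <- (ht[k] == "row" && hi[k] == tpos[1] - 1) ||
                    (ht[k] == "column" && hi[k] == tpos[2] - 1)
          rows[[length(rows) + 1L]] <- data.frame(
            onset = t_cursor, duration = spec$highlight_duration,
            highlight_type = ht[k], highlight_index = hi[k],
            is_target = is_tgt, cycle_index = cyc_global,
            block_index = b, target_symbol = targets[b],
            stringsAsFactors = FALSE)
          t_cursor <- t_cursor + spec$highlight_duration +
            stats::runif(1, spec$iti_range[1], spec$iti_range[2])
        }
      }
    }
    tab <- do.call(rbind, rows)
    class(tab) <- c("trial_table", "data.frame")
    tab
  })
}

# half-cosine bump of given duration (s) on a dt grid, unit peak
bump <- function(duration, dt) {
  n <- max(2L, round(duration / dt))
  0.5 - 0.5 * cos(2 * pi * seq(0, 1, length.out = n))
}

#' Generate latent neural source time series for a trial table
#'
#' Every trial evokes a small early response in the "visual" source; target
#' trials additionally evoke a P300-like bump in the "P300" source at a
#' latency drawn uniformly from 250-400 ms with lognormal amplitude jitter.
#' Sources are sampled at `dt` (default 0.1 s).
#'
#' @param trials A trial table from [generate_paradigm()].
#' @param seed Integer seed.
#' @param dt Source sampling interval (s).
#' @return A `session_truth` list: `sources` (2 x time matrix, rows
#'   "visual"/"p300"), `dt`, `latencies` (per target trial, s; NA for
#'   non-targets), `amplitudes`, and the seed.
#' @export
generate_sources <- function(trials, seed = 1L, dt = 0.1) {
  stopifnot(inherits(trials, "data.frame"))
  with_seed(seed, {
    dur <- max(trials$onset) + 20
    n <- ceiling(dur / dt)
    src <- matrix(0, 2, n, dimnames = list(c("visual", "p300"), NULL))
    lat <- rep(NA_real_, nrow(trials))
    amp <- rep(NA_real_, nrow(trials))
    vis_b <- bump(0.2, dt)
    p3_b <- bump(0.35, dt)
    for (i in seq_len(nrow(trials))) {
      on_idx <- round(trials$onset[i] / dt) + 1L
      a_vis <- stats::rlnorm(1, log(0.5), 0.2)
      idx <- on_idx + seq_along(vis_b) - 1L
      src[1, idx] <- src[1, idx] + a_vis * vis_b
      if (trials$is_target[i]) {
        lat[i] <- stats::runif(1, 0.25, 0.40)
        amp[i] <- stats::rlnorm(1, log(1), 0.2)
        pidx <- on_idx + round(lat[i] / dt) + seq_along(p3_b) - 1L
        src[2, pidx] <- src[2, pidx] + amp[i] * p3_b
      }
    }
    structure(list(sources = src, dt = dt, latencies = lat,
                   amplitudes = amp, seed = as.integer(seed)),
              class = "session_truth")
  })
}

# 1/f-shaped noise, one row per channel, unit variance per row. Shaped in
# the frequency domain at an FFT-friendly padded length, then truncated.
pink_noise <- function(nchan, n, fs) {
  np <- stats::nextn(n, c(2, 3, 5))
  out <- matrix(0, nchan, n)
  fr <- c(1e-3, seq_len(floor(np / 2)) * fs / np)
  for (ch in seq_len(nchan)) {
    spec <- stats::rnorm(length(fr)) + 1i * stats::rnorm(length(fr))
    spec <- spec / sqrt(pmax(fr, 0.5))
    full <- c(spec, Conj(rev(spec[2:(length(spec) - (np %% 2 == 0))])))
    x <- Re(stats::fft(full[seq_len(np)], inverse = TRUE))[seq_len(n)]
    out[ch, ] <- x / stats::sd(x)
  }
  out
}

#' Generate a paired EEG + BOLD speller session
#'
#' Builds the trial table and latent sources, then renders: EEG as a seeded
#' linear source mixture (unit-norm columns) upsampled to `eeg_fs` plus 1/f
#' noise at the requested SNR; BOLD as the per-voxel Balloon-model response
#' (TR 0.2 s) to the voxel's region source plus white noise at the BOLD SNR.
#' Voxels are partitioned into a "p300" region, a "visual" region and null
#' voxels. SNR is evoked-signal variance over noise variance, in dB.
#'
#' @param spec A [paradigm_spec()].
#' @param seed Integer seed; identical seeds give bit-identical sessions.
#' @param eeg_snr_db,bold_snr_db Per-modality SNR (dB).
#' @param n_channels Number of EEG channels (>= 4).
#' @param n_voxels Number of voxels (>= 10).
#' @param eeg_fs EEG sampling rate (Hz).
#' @param TR BOLD sampling interval (s).
#' @param mixing Optional fixed n_channels x 2 source-mixing matrix
#'   (unit-norm columns); lets synthetic "subjects" share their forward
#'   model while differing in everything else.
#' @return A `speller_session` list: `eeg` ([eeg_recording()]), `bold`
#'   (list of [bold_ts()]), `trials`, `truth` (`session_truth` extended
#'   with the mixing matrix, voxel->region map and per-voxel Balloon
#'   parameters), and the acquisition settings.
#' @export
generate_session <- function(spec, seed = 1L, eeg_snr_db = 10,
                             bold_snr_db = 10, n_channels = 8,
                             n_voxels = 20, eeg_fs = 250, TR = 0.2,
                             mixing = NULL) {
  stopifnot(inherits(spec, "paradigm_spec"))
  if (n_channels < 4) stop("n_channels must be >= 4")
  if (n_voxels < 10) stop("n_voxels must be >= 10")
  if (!is.finite(eeg_snr_db) || !is.finite(bold_snr_db)) stop("SNR must be finite")
  trials <- generate_paradigm(spec, seed = seed)
  truth <- generate_sources(trials, seed = seed + 1L)
  with_seed(seed + 2L, {
    src <- truth$sources
    nt_src <- ncol(src)
    # --- EEG: mix sources, upsample to eeg_fs by linear interpolation ---
    A <- mixing %||% {
      M <- matrix(stats::rnorm(n_channels * 2), n_channels, 2)
      sweep(M, 2, sqrt(colSums(M^2)), "/")
    }
    stopifnot(nrow(A) == n_channels, ncol(A) == 2)
    n_eeg <- ceiling(nt_src * truth$dt * eeg_fs)
    t_src <- (seq_len(nt_src) - 1) * truth$dt
    t_eeg <- (seq_len(n_eeg) - 1) / eeg_fs
    src_up <- rbind(stats::approx(t_src, src[1, ], xout = t_eeg, rule = 2)$y,
                    stats::approx(t_src, src[2, ], xout = t_eeg, rule = 2)$y)
    clean <- A %*% src_up
    noise <- pink_noise(n_channels, n_eeg, eeg_fs)
    sig_var <- mean(apply(clean, 1, stats::var))
    nscale <- sqrt(sig_var / 10^(eeg_snr_db / 10))
    eeg <- eeg_recording(clean + nscale * noise, eeg_fs)
    # --- BOLD: region-mapped Balloon responses ---
    n_p300 <- max(3L, round(n_voxels * 0.3))
    n_vis <- max(3L, round(n_voxels * 0.3))
    region <- c(rep("p300", n_p300), rep("visual", n_vis),
                rep("null", n_voxels - n_p300 - n_vis))
    dec <- max(1L, round(TR / truth$dt))
    vox_params <- vector("list", n_voxels)
    drives <- matrix(0, n_voxels, nt_src)
    for (v in seq_len(n_voxels)) {
      jit <- function(x, f = 0.15) x * stats::runif(1, 1 - f, 1 + f)
      vox_params[[v]] <- balloon_params(tau = jit(0.98), E0 = jit(0.34),
                                        kappa = jit(0.65), gamma = jit(0.41))
      drives[v, ] <- switch(region[v], p300 = src[2, ], visual = src[1, ],
                            null = rep(0, nt_src))
    }
    all_bold <- simulate_hemodynamics_multi(drives, truth$dt, vox_params)
    clean_bold <- lapply(seq_len(n_voxels),
                         function(v) all_bold[v, seq(dec, nt_src, by = dec)])
    active_sd <- mean(vapply(which(region != "null"),
                             function(v) stats::sd(clean_bold[[v]]), 0))
    noise_sd_bold <- active_sd / sqrt(10^(bold_snr_db / 10))
    bold <- vector("list", n_voxels)
    for (v in seq_len(n_voxels)) {
      y <- clean_bold[[v]] + stats::rnorm(length(clean_bold[[v]]), sd = noise_sd_bold)
      bold[[v]] <- bold_ts(y, TR, space_id = sprintf("vox%02d_%s", v, region[v]))
    }
    truth$mixing <- A
    truth$region <- region
    truth$vox_params <- vox_params
    truth$session_seed <- as.integer(seed)
    structure(list(eeg = eeg, bold = bold, trials = trials, truth = truth,
                   spec = spec, TR = TR, eeg_fs = eeg_fs),
              class = "speller_session")
  })
}

#' Write a session to disk in standard formats
#'
#' EEG as a plain-array RDS container plus channel metadata JSON, BOLD as a
#' NIfTI-1 4D image (voxels laid out along x), events as TSV, ground truth
#' summary as JSON.
#'
#' @param session A `speller_session`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  paths$events <- file.path(dir, "events.tsv")
  ev <- session$trials
  ev$trial_type <- ifelse(ev$is_target, "target", "nontarget")
  utils::write.table(ev[, c("onset", "duration", "trial_type",
                            "highlight_index", "is_target",
                            "highlight_type", "cycle_index", "block_index",
                            "target_symbol")],
                     paths$events, sep = "\t", row.names = FALSE, quote = FALSE)
  paths$eeg <- file.path(dir, "eeg.rds")
  saveRDS(session$eeg, paths$eeg)
  nvox <- length(session$bold)
  ntime <- length(session$bold[[1]]$values)
  vol <- array(0, c(nvox, 1, 1, ntime))
  for (v in seq_len(nvox)) vol[v, 1, 1, ] <- session$bold[[v]]$values
  paths$bold <- file.path(dir, "bold.nii.gz")
  RNifti::writeNifti(RNifti::asNifti(vol, pixdim = c(3, 3, 3, session$TR)),
                     paths$bold)
  paths$truth <- file.path(dir, "truth.json")
  jsonlite::write_json(list(seed = session$truth$session_seed,
                            TR = session$TR, eeg_fs = session$eeg_fs,
                            region = session$truth$region,
                            latencies = session$truth$latencies),
                       paths$truth, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(paths)
}

#' Read a session written by [write_session()]
#'
#' @param dir Directory holding `eeg.rds`, `bold.nii.gz`, `events.tsv` (and
#'   optionally `truth.json`).
#' @return A `speller_session` (without the generator-internal ground truth
#'   beyond what `truth.json` carries).
#' @export
read_session <- function(dir) {
  eeg <- readRDS(file.path(dir, "eeg.rds"))
  ev <- utils::read.delim(file.path(dir, "events.tsv"))
  ev$is_target <- as.logical(ev$is_target)
  class(ev) <- c("trial_table", "data.frame")
  img <- RNifti::readNifti(file.path(dir, "bold.nii.gz"))
  nvox <- dim(img)[1]
  truth <- NULL
  tj <- file.path(dir, "truth.json")
  region <- rep("unknown", nvox)
  TR <- NULL
  if (file.exists(tj)) {
    truth <- jsonlite::read_json(tj, simplifyVector = TRUE)
    if (!is.null(truth$region)) region <- truth$region
    TR <- truth$TR
  }
  # fall back to the NIfTI time-step header field
  TR <- TR %||% RNifti::pixdim(img)[4]
  bold <- lapply(seq_len(nvox), function(v)
    bold_ts(img[v, 1, 1, ], TR, space_id = sprintf("vox%02d_%s", v, region[v])))
  structure(list(eeg = eeg, bold = bold, trials = ev, truth = truth,
                 spec = NULL, TR = TR, eeg_fs = eeg$fs),
            class = "speller_session")
}
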