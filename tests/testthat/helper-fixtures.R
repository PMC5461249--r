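# Shared small fixtures for pipeline-level tests. Everything is generated
# in code; sizes are kept small so the default run stays fast.

# pipeline configuration scaled for tests: reduced frequency grids and a
# coarser TFR time axis
test_config <- function(seed = 9, folds = 4) {
  pipeline_config(eeg_freqs = default_freqs("eeg", 10),
                  fmri_freqs = default_freqs("fmri", 6),
                  R = 3, L = c(3, 3, 3), K = c(3, 3, 3),
                  eeg_decim = 25L, fmri_decim = 4L,
                  seed = seed, folds = folds)
}

# small high-SNR speller session (6 blocks x 3 cycles, 12 voxels)
test_session <- function(seed = 42, n_blocks = 6, cycles = 3,
                         snr = 18, n_voxels = 12) {
  generate_session(paradigm_spec(n_blocks = n_blocks, cycles_per_block = cycles),
                   seed = seed, eeg_snr_db = snr, bold_snr_db = snr,
                   n_channels = 8, n_voxels = n_voxels)
}

# memoized expensive fixture: one session with trained chain and tensors,
# reused by several pipeline tests within a single run
.fixture_env <- new.env(parent = emptyenv())
trained_chain <- function() {
  if (is.null(.fixture_env$chain)) {
    ses <- test_session()
    cfg <- test_config()
    trses <- subset_session(ses, 1:4)
    st <- session_tensors(trses, cfg)
    fit <- fit_linkage(trses, config = cfg, tensors = st)
    .fixture_env$chain <- list(session = ses, train = trses,
                               test = subset_session(ses, 5:6),
                               config = cfg, tensors = st, fit = fit)
  }
  .fixture_env$chain
}
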