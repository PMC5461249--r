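test_that("a 48-cycle session has the canonical trial counts", {
  tab <- generate_paradigm(paradigm_spec(n_blocks = 4, cycles_per_block = 12),
                           seed = 7)
  expect_equal(nrow(tab), 576)
  expect_equal(sum(tab$is_target), 96)
  expect_equal(sum(!tab$is_target), 480)
  expect_equal(sum(tab$is_target) / sum(!tab$is_target), 0.2)
  expect_true(all(tab$duration == 0.5))
  itis <- diff(tab$onset) - 0.5
  expect_true(all(itis >= 2 & itis <= 5))
  expect_true(all(diff(tab$onset) > 0))
})

test_that("cycle structure and count scaling are exact", {
  for (cyc in c(1, 3)) {
    tab <- generate_paradigm(paradigm_spec(n_blocks = 2, cycles_per_block = cyc),
                             seed = 1)
    expect_equal(nrow(tab), 2 * cyc * 12)
    expect_equal(sum(tab$is_target), 2 * cyc * 2)
    per_cycle <- split(tab, tab$cycle_index)
    for (pc in per_cycle) {
      expect_equal(nrow(pc), 12)
      expect_equal(sum(pc$is_target), 2)
      expect_equal(sort(pc$highlight_index[pc$highlight_type == "row"]), 0:5)
      expect_equal(sort(pc$highlight_index[pc$highlight_type == "column"]), 0:5)
    }
  }
  expect_error(generate_paradigm(paradigm_spec(n_blocks = 2,
                                               targets = c("A", "~")), 1),
               "targets")
})

test_that("paradigm tables are deterministic per seed", {
  spec <- paradigm_spec(n_blocks = 2, cycles_per_block = 2)
  expect_identical(generate_paradigm(spec, 3), generate_paradigm(spec, 3))
  expect_false(identical(generate_paradigm(spec, 3), generate_paradigm(spec, 4)))
})

test_that("sources respect P300 latency bounds and target specificity", {
  tab <- generate_paradigm(paradigm_spec(n_blocks = 4, cycles_per_block = 12),
                           seed = 9)
  tru <- generate_sources(tab, seed = 10)
  lat <- tru$latencies[tab$is_target]
  expect_length(lat, 96)
  expect_gte(min(lat), 0.25)
  expect_lte(max(lat), 0.40)
  expect_true(all(is.na(tru$latencies[!tab$is_target])))
  # non-target trials evoke nothing in the P300 source
  p3 <- tru$sources["p300", ]
  nt_idx <- round(tab$onset[!tab$is_target][1:20] / tru$dt) + 1
  # window ends before the next trial can start (ITI >= 2 s)
  for (k in nt_idx) {
    prev_target_near <- any(abs(tab$onset[tab$is_target] -
                                (k - 1) * tru$dt) < 1.5)
    if (!prev_target_near) expect_lt(max(p3[k:(k + 9)]), 1e-12)
  }
  # target epochs carry much larger P300-source energy
  ep_amp <- function(idx) vapply(idx, function(on) {
    k <- round(on / tru$dt) + 1
    max(p3[k:(k + 9)])
  }, 0)
  tt <- stats::t.test(ep_amp(tab$onset[tab$is_target]),
                      ep_amp(tab$onset[!tab$is_target]),
                      alternative = "greater")
  expect_lt(tt$p.value, 1e-6)
})

test_that("sessions are reproducible and carry the planted structure", {
  spec <- paradigm_spec(n_blocks = 2, cycles_per_block = 3)
  s1 <- generate_session(spec, seed = 3, eeg_snr_db = 15, bold_snr_db = 15,
                         n_voxels = 12)
  s2 <- generate_session(spec, seed = 3, eeg_snr_db = 15, bold_snr_db = 15,
                         n_voxels = 12)
  expect_identical(s1, s2)
  # trial-averaged target-minus-nontarget EEG difference peaks in the P300 window
  ep <- epoch(s1$eeg, s1$trials, c(0, 1))
  dif <- abs(apply(ep$data[s1$trials$is_target, , ], 3, mean) -
             apply(ep$data[!s1$trials$is_target, , ], 3, mean))
  peak_t <- ep$times[which.max(dif)]
  expect_gte(peak_t, 0.25)
  expect_lte(peak_t, 0.75)   # latency + response width
  # P300-region voxels respond to targets more than null voxels
  bmat <- do.call(rbind, lapply(s1$bold, function(b) b$values))
  epb <- epoch(bmat, s1$trials, c(0, 8), fs = 1 / s1$TR)
  resp <- apply(epb$data[, , epb$times >= 2 & epb$times <= 6], c(1, 2), mean)
  tgt <- s1$trials$is_target
  effect <- apply(resp, 2, function(v) mean(v[tgt]) - mean(v[!tgt]))
  p300_vox <- which(s1$truth$region == "p300")
  null_vox <- which(s1$truth$region == "null")
  expect_gt(min(effect[p300_vox]), max(effect[null_vox]))
})

test_that("argument contracts of the session generator hold", {
  spec <- paradigm_spec(n_blocks = 1, cycles_per_block = 1)
  expect_error(generate_session(spec, n_channels = 2), "n_channels")
  expect_error(generate_session(spec, n_voxels = 5), "n_voxels")
  expect_error(generate_session(spec, eeg_snr_db = Inf), "SNR")
  expect_error(paradigm_spec(iti_range = c(5, 2)), "iti_range")
})

test_that("session files round-trip through standard formats", {
  spec <- paradigm_spec(n_blocks = 1, cycles_per_block = 1)
  ses <- generate_session(spec, seed = 5, n_voxels = 10)
  dir <- file.path(tempdir(), "bcilink-session")
  paths <- write_session(ses, dir)
  ev <- read.delim(paths$events)
  expect_equal(nrow(ev), nrow(ses$trials))
  expect_true(all(c("onset", "duration", "trial_type") %in% names(ev)))
  vol <- RNifti::readNifti(paths$bold)
  expect_equal(dim(vol)[4], length(ses$bold[[1]]$values))
  expect_equal(vol[1, 1, 1, ], ses$bold[[1]]$values, tolerance = 1e-6)
  truth <- jsonlite::read_json(paths$truth)
  expect_equal(truth$seed, 5)
  back <- read_session(dir)
  expect_s3_class(back, "speller_session")
  expect_equal(back$trials$onset, ses$trials$onset)
  expect_equal(back$trials$block_index, ses$trials$block_index)
  expect_equal(back$eeg$samples, ses$eeg$samples)
  expect_equal(back$TR, ses$TR)
  expect_equal(back$bold[[2]]$values, ses$bold[[2]]$values, tolerance = 1e-6)
  unlink(dir, recursive = TRUE)
})
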