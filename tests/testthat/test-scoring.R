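# Epoch features, rule classification, micro-arousal refinement, artefacts.

make_feat <- function(emg, swa = 10, theta_dom = 0.5) {
  data.frame(epoch = seq_along(emg), emg_rms = emg, frontal_swa_amp = swa,
             occ_theta_power = theta_dom * 100, occ_delta_power = 100,
             theta_dominance = theta_dom)
}

thr_fixed <- structure(list(emg_hi = 30, emg_lo = 15, swa_amp_min = 20,
                            theta_dominance_min = 1.5, artefact_z = 8),
                       class = "vs_thresholds")

test_that("epoch features recover known signal properties", {
  fs <- 256
  t <- (0:(fs * 16 - 1)) / fs
  rec <- vs_recording(list(frontal = 50 * sin(2 * pi * 2 * t),
                           occipital = 30 * sin(2 * pi * 8 * t),
                           emg = 100 * sqrt(2) * sin(2 * pi * 25 * t)),
                      fs = fs)
  f <- compute_epoch_features(rec)
  expect_equal(nrow(f), 4)
  expect_equal(f$emg_rms, rep(100, 4), tolerance = 0.01)
  # pure 8 Hz occipital sine: theta dominates delta overwhelmingly
  expect_true(all(f$theta_dominance > 10))
  # 2 Hz frontal sine: SWA envelope amplitude ~ the 50 µV peak
  expect_equal(f$frontal_swa_amp, rep(50, 4), tolerance = 0.1)

  rec0 <- vs_recording(list(frontal = numeric(fs * 8),
                            occipital = numeric(fs * 8),
                            emg = numeric(fs * 8)), fs = fs)
  f0 <- compute_epoch_features(rec0)
  expect_true(all(f0$emg_rms == 0) && all(f0$frontal_swa_amp == 0))
  expect_error(compute_epoch_features(
    vs_recording(list(frontal = rnorm(100), occipital = rnorm(100),
                      emg = rnorm(100)), fs = 256)), "epoch")
})

test_that("classification follows the EMG-first rule precedence", {
  # high EMG -> WAKE regardless of spectral content
  expect_equal(classify_epochs(make_feat(100, swa = 100, theta_dom = 5),
                               thr_fixed), "WAKE")
  # low EMG + high SWA + low theta dominance -> NREM
  expect_equal(classify_epochs(make_feat(5, swa = 100, theta_dom = 0.3),
                               thr_fixed), "NREM")
  # low EMG + theta dominance -> REM (checked before NREM)
  expect_equal(classify_epochs(make_feat(5, swa = 100, theta_dom = 3),
                               thr_fixed), "REM")
  # intermediate EMG defaults to NREM
  expect_equal(classify_epochs(make_feat(20, swa = 5, theta_dom = 3),
                               thr_fixed), "NREM")
})

test_that("micro-arousal sandwich and 5-epoch rules are exact", {
  expect_equal(refine_microarousals(c("NREM", "WAKE", "NREM")),
               c("NREM", "MICRO_AROUSAL", "NREM"))
  expect_equal(refine_microarousals(c("REM", "WAKE", "NREM")),
               c("REM", "MICRO_AROUSAL", "NREM"))
  # four consecutive still qualify; five do not
  expect_equal(refine_microarousals(c("NREM", rep("WAKE", 4), "NREM")),
               c("NREM", rep("MICRO_AROUSAL", 4), "NREM"))
  long <- c("NREM", rep("WAKE", 5), "NREM")
  expect_equal(refine_microarousals(long), long)
  # no sleep flank at the recording edge: unchanged
  expect_equal(refine_microarousals(c("WAKE", "WAKE", "NREM")),
               c("WAKE", "WAKE", "NREM"))
  # right flank must be NREM (WAKE-REM boundary does not qualify)
  expect_equal(refine_microarousals(c("NREM", "WAKE", "REM")),
               c("NREM", "WAKE", "REM"))
})

test_that("refinement conserves epoch count and only toggles WAKE/MICRO_AROUSAL", {
  set.seed(21)
  for (i in 1:25) {
    lab <- sample(c("WAKE", "NREM", "REM"), 60, replace = TRUE)
    out <- refine_microarousals(lab)
    expect_equal(length(out), length(lab))
    changed <- which(out != lab)
    expect_true(all(lab[changed] == "WAKE" & out[changed] == "MICRO_AROUSAL"))
    # fixpoint: applying again changes nothing
    expect_identical(refine_microarousals(out), out)
  }
})

test_that("artefact flags catch inserted transients and never change labels", {
  fs <- 256
  set.seed(22)
  x <- rnorm(fs * 4 * 30, sd = 20)
  x[fs * 4 * 10 + 50] <- 20 * max(abs(x))  # gross transient in epoch 11
  rec <- vs_recording(list(frontal = x, occipital = rnorm(length(x), sd = 20),
                           emg = rnorm(length(x), sd = 20)), fs = fs)
  flags <- mark_artefacts(rec, thr_fixed)
  expect_true(flags[11, "frontal"])
  expect_lt(sum(flags[, "frontal"]), 3)    # clean epochs not flagged
  hyp <- score_recording(rec)
  expect_equal(length(hyp$labels), 30)     # flagged epoch keeps a state label
  expect_false(any(is.na(hyp$labels)))
})

test_that("auto-calibrated scoring recovers generator ground truth", {
  cfg <- quick_config(seed = 30, duration_h = 0.5)
  lab <- generate_hypnogram(cfg)
  s <- synthesize_signals(lab, cfg)
  hyp <- score_recording(s$recording)
  keep <- hyp$labels != "MICRO_AROUSAL"
  expect_gt(mean(hyp$labels[keep] == lab[keep]), 0.9)
  # drug-window wake with added slow waves must still score WAKE
  d <- apply_drug_effects(s$recording, lab, cfg, s$truth)
  hyp_d <- score_recording(d$recording)
  win <- cfg$drug_window
  ep_start <- (seq_along(lab) - 1) * 4
  wake_in <- ep_start >= win[1] & ep_start + 4 <= win[2] & lab == "WAKE"
  expect_gt(mean(hyp_d$labels[wake_in] == "WAKE"), 0.9)
})
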