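# Synthetic study generator: determinism, chain statistics, signal structure,
# drug effects, pupil geometry, and on-disk bundles.

test_that("hypnograms are deterministic under seed and validate bout means", {
  cfg <- quick_config(seed = 42, duration_h = 1)
  expect_identical(generate_hypnogram(cfg), generate_hypnogram(cfg))
  expect_error(quick_config(mean_bout_s = c(wake = -1, nrem = 280, rem = 80)),
               "positive")
})

test_that("degenerate chain with only waking bouts yields an all-WAKE hypnogram", {
  # with no NREM->REM and REM->WAKE certain, making wake bouts dominate and
  # sleep bouts vanishing keeps the chain in WAKE for whole short recordings
  cfg <- quick_config(seed = 1, duration_h = 0.1,
                      mean_bout_s = c(wake = 1e9, nrem = 1e-6, rem = 1e-6))
  expect_true(all(generate_hypnogram(cfg) == "WAKE"))
})

test_that("state fractions match a 10x longer run of the same chain", {
  cfg <- synth_config(seed = 10, duration_h = 24)
  lab <- generate_hypnogram(cfg)
  cfg10 <- synth_config(seed = 11, duration_h = 240)
  lab10 <- generate_hypnogram(cfg10)
  for (s in c("WAKE", "NREM", "REM")) {
    expect_lt(abs(mean(lab == s) - mean(lab10 == s)), 0.10)
  }
})

test_that("background-only channels show monotone 1/f spectral decay", {
  cfg <- quick_config(seed = 2, duration_h = 0.1, delta_amp_nrem = 0,
                      theta_amp_rem = 0, theta_amp_wake_occ = 0,
                      wave_rate_nrem = 0)
  s <- synthesize_signals(generate_hypnogram(cfg), cfg,
                          channels = c("frontal", "occipital", "emg"))
  sp <- epoch_spectra(s$recording, "frontal")
  mp <- colMeans(sp$power)
  # smoothed decade-band means decrease with frequency
  f <- sp$freq
  bands <- list(c(1, 4), c(4, 16), c(16, 64), c(64, 120))
  bm <- sapply(bands, function(b) mean(mp[f >= b[1] & f < b[2]]))
  expect_true(all(diff(bm) < 0))
  # and the fitted log-log slope recovers the configured exponent
  fit <- fit_spectral_slope(mp[-1], f[-1], range = c(5, 120), log_freq = TRUE)
  expect_equal(-fit$slope, cfg$background_exponent, tolerance = 0.15)
})

test_that("NREM frontal slow-wave power exceeds wake power; EMG grades by state", {
  cfg <- quick_config(seed = 3, duration_h = 0.25)
  lab <- generate_hypnogram(cfg)
  s <- synthesize_signals(lab, cfg)
  sp <- epoch_spectra(s$recording, "frontal")
  swa <- band_power(sp, c(0.5, 4))
  expect_gt(mean(swa[lab == "NREM"]), mean(swa[lab == "WAKE"]))
  emg <- sqrt(colMeans(vigilstate:::epoch_matrix(s$recording$channels$emg,
                                                 256, 4)^2))
  expect_gt(mean(emg[lab == "WAKE"]), mean(emg[lab == "NREM"]))
  if (any(lab == "REM")) expect_gt(mean(emg[lab == "NREM"]), mean(emg[lab == "REM"]))
})

test_that("injected OFF intervals are spike-free by construction", {
  cfg <- quick_config(seed = 4, duration_h = 0.25)
  s <- synthesize_signals(generate_hypnogram(cfg), cfg)
  offs <- s$truth$off_periods
  expect_gt(nrow(offs), 5)
  spk <- s$recording$spike_times
  inside <- sum(vapply(seq_len(nrow(offs)), function(i)
    sum(spk >= offs$onset[i] & spk < offs$offset[i]), 0))
  expected <- cfg$baseline_spike_rate * sum(offs$offset - offs$onset)
  expect_lt(inside / expected, 0.05)
})

test_that("wave injection is centred: each truth peak is a local maximum", {
  cfg <- quick_config(seed = 5, duration_h = 0.25, delta_amp_nrem = 0,
                      background_rms = c(frontal = 15, occipital = 15,
                                         lfp = 0.001))
  s <- synthesize_signals(generate_hypnogram(cfg), cfg, channels = "lfp")
  w <- s$truth$waves
  expect_gt(nrow(w), 0)
  x <- s$recording$channels$lfp
  for (i in seq_len(min(nrow(w), 20))) {
    ci <- round(w$peak_t[i] * 256) + 1
    expect_equal(x[ci], max(x[(ci - 5):(ci + 5)]))
    expect_equal(x[ci], w$amplitude[i], tolerance = 0.02)
  }
})

test_that("drug effects: identity at unit gains, locality, theta suppression", {
  cfg <- quick_config(seed = 6, duration_h = 0.25)
  lab <- generate_hypnogram(cfg)
  s <- synthesize_signals(lab, cfg)
  fs <- 256

  id_cfg <- quick_config(seed = 6, duration_h = 0.25, drug_swa_gain = 1,
                         drug_theta_gain = 1)
  ident <- apply_drug_effects(s$recording, lab, id_cfg, s$truth)
  expect_identical(ident$recording$channels, s$recording$channels)

  z_cfg <- quick_config(seed = 6, duration_h = 0.25, drug_theta_gain = 0)
  z <- apply_drug_effects(s$recording, lab, z_cfg, s$truth)
  win <- z_cfg$drug_window
  ep_start <- (seq_along(lab) - 1) * 4
  wake_in <- which(ep_start >= win[1] & ep_start + 4 <= win[2] & lab == "WAKE")
  expect_gt(length(wake_in), 5)
  th_v <- band_power(epoch_spectra(s$recording, "occipital"), c(7, 12.5))[wake_in]
  th_d <- band_power(epoch_spectra(z$recording, "occipital"), c(7, 12.5))[wake_in]
  expect_lt(mean(th_d) / mean(th_v), 0.10)

  out_idx <- c(seq_len(win[1] * fs - fs), (win[2] * fs + fs):(length(lab) * 4 * fs))
  expect_identical(z$recording$channels$occipital[out_idx],
                   s$recording$channels$occipital[out_idx])
  expect_identical(z$recording$channels$emg, s$recording$channels$emg)

  expect_error(apply_drug_effects(s$recording, lab,
                                  synth_config(seed = 6, duration_h = 2),
                                  s$truth),
               "window")
})

test_that("drug SWA gain approximately multiplies wake-window band power", {
  cfg <- quick_config(seed = 7, duration_h = 0.25, drug_swa_gain = 2)
  lab <- generate_hypnogram(cfg)
  s <- synthesize_signals(lab, cfg)
  d <- apply_drug_effects(s$recording, lab, cfg, s$truth)
  win <- cfg$drug_window
  ep_start <- (seq_along(lab) - 1) * 4
  wake_in <- which(ep_start >= win[1] & ep_start + 4 <= win[2] & lab == "WAKE")
  expect_gt(length(wake_in), 10)
  sw_v <- band_power(epoch_spectra(s$recording, "frontal"), c(0.5, 4))[wake_in]
  sw_d <- band_power(epoch_spectra(d$recording, "frontal"), c(0.5, 4))[wake_in]
  expect_equal(mean(sw_d) / mean(sw_v), 2, tolerance = 0.35)
  expect_true(d$truth$drug)
  expect_gt(nrow(d$truth$drug_waves), 0)
})

test_that("noiseless pupil geometry reproduces the true diameter exactly", {
  cfg <- quick_config(seed = 8, duration_h = 0.02, pupil_jitter_px = 0,
                      dropout_frac = 0)
  p <- synthesize_pupil(cfg, "vehicle")
  d <- compute_diameter(p$trace)$frames$diameter
  expect_equal(d, p$true_diameter, tolerance = 1e-12)
  # vehicle condition has no transient
  expect_lt(max(d) / stats::median(d), 1.05)
})

test_that("dropout fraction matches the configured rate", {
  cfg <- quick_config(seed = 9, duration_h = 0.1, dropout_frac = 0.2)
  p <- synthesize_pupil(cfg, "vehicle")
  lik <- p$trace$frames[grep("_likelihood$", names(p$trace$frames))]
  frac <- mean(apply(as.matrix(lik) < 0.99, 1, any))
  n <- nrow(p$trace$frames)
  expect_lt(abs(frac - 0.2), 3 * sqrt(0.2 * 0.8 / n) + 1 / n)
})

test_that("study bundles round trip and share the pre-injection baseline", {
  cfg <- quick_config(seed = 12, duration_h = 0.1)
  dir <- tempfile()
  expect_error(generate_study(cfg, dir), dir)
  dir.create(dir)
  generate_study(cfg, dir)
  v <- read_study(file.path(dir, "vehicle"))
  d <- read_study(file.path(dir, "drug"))
  expect_equal(v$hypnogram$labels, d$hypnogram$labels)
  # pre-injection samples identical (EDF quantization aside, scaling may
  # differ between arms, so compare against a shared tolerance)
  pre <- seq_len(cfg$drug_window[1] * 256 - 256)
  expect_equal(v$recording$channels$frontal[pre],
               d$recording$channels$frontal[pre], tolerance = 1e-3)
  # round trip through the io module preserves signals to quantization
  raw <- synthesize_signals(generate_hypnogram(cfg), cfg)
  expect_equal(v$recording$channels$lfp[pre], raw$recording$channels$lfp[pre],
               tolerance = 0.1)
  expect_equal(v$truth$waves$peak_t, raw$truth$waves$peak_t)
})

test_that("configs validate their invariants", {
  expect_error(quick_config(dropout_frac = 1), "dropout")
  expect_error(quick_config(emg_rms = c(wake = 10, nrem = 20, rem = 8)), "graded")
  expect_error(synth_config(duration_h = 0.1), "drug_window")
  expect_error(quick_config(fs = 250.3), "epoch")
  expect_error(quick_config(drug_theta_gain = 2), "theta_gain")
})
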