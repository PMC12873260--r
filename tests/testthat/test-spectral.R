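# Epoch spectra, band power, aperiodic slope, and modulation index.

test_that("4-s epochs at 256 Hz give 481 bins at exactly 0.25 Hz spacing", {
  rec <- vs_recording(list(frontal = rnorm(256 * 40)), fs = 256)
  sp <- epoch_spectra(rec)
  expect_equal(ncol(sp$power), 481)
  expect_equal(unique(round(diff(sp$freq), 10)), 0.25)
  expect_equal(range(sp$freq), c(0, 120))
  expect_true(all(sp$power >= 0))
  expect_error(epoch_spectra(vs_recording(list(frontal = rnorm(1000)),
                                          fs = 200)), "256")
})

test_that("a 10 Hz sinusoid peaks at the 10.00 Hz bin and sums to its variance", {
  fs <- 256
  t <- (0:(fs * 4 - 1)) / fs
  rec <- vs_recording(list(frontal = sin(2 * pi * 10 * t)), fs = fs)
  sp <- epoch_spectra(rec)
  expect_equal(sp$freq[which.max(sp$power[1, ])], 10)
  expect_equal(sum(sp$power[1, ]), 0.5, tolerance = 0.01)
})

test_that("white-noise band-summed power matches the signal variance", {
  set.seed(31)
  x <- rnorm(256 * 4 * 20, sd = 3)
  rec <- vs_recording(list(frontal = x), fs = 256)
  # full 0-128 Hz sum equals variance (Parseval with window correction)
  sp <- vigilstate:::epoch_spectra_matrix(x, 256, 4, f_max = 128)
  expect_equal(mean(colSums(sp$power)), 9, tolerance = 0.05 * 9)
})

test_that("band power uses inclusive edges and is additive over disjoint bands", {
  fs <- 256
  t <- (0:(fs * 4 - 1)) / fs
  rec <- vs_recording(list(frontal = sin(2 * pi * 2 * t)), fs = fs)
  sp <- epoch_spectra(rec)
  total <- sum(sp$power[1, ])
  expect_equal(band_power(sp, c(0.5, 4))[1], total, tolerance = 1e-6)
  lo <- band_power(sp, c(0.5, 4))
  hi <- band_power(sp, c(4.25, 120))
  expect_equal(lo + hi + band_power(sp, c(0, 0.25)),
               band_power(sp, c(0, 120)), tolerance = 1e-12)
  expect_error(band_power(sp, c(100, 140)), "range")
})

test_that("band-power time course averages states and excludes artefacts", {
  power <- matrix(0, nrow = 6, ncol = 481)
  power[, 9] <- c(100, 100, 50, 100, 100, 100)  # bin 9 = 2 Hz
  sp <- structure(list(power = power, freq = seq(0, 120, by = 0.25),
                       derivation = "frontal", epoch_s = 4),
                  class = "vs_spectra")
  art <- matrix(FALSE, 6, 1, dimnames = list(NULL, "frontal"))
  art[3, 1] <- TRUE
  hyp <- vs_hypnogram(rep("NREM", 6), artefact = art)
  tc <- band_power_timecourse(sp, hyp, c(0.5, 4), state = "NREM",
                              bin_minutes = 1)
  # artefact epoch (the 50) excluded: mean of the five 100s
  expect_equal(tc$value[1], 100)
  expect_equal(tc$n_epochs[1], 5)
  # normalisation to percent of a reference
  tc2 <- band_power_timecourse(sp, hyp, c(0.5, 4), state = "NREM",
                               bin_minutes = 1, reference = 50)
  expect_equal(tc2$value[1], 200)
  # bins with no qualifying epoch are missing
  hyp_w <- vs_hypnogram(rep("WAKE", 6))
  tc3 <- band_power_timecourse(sp, hyp_w, c(0.5, 4), state = "NREM",
                               bin_minutes = 1)
  expect_true(is.na(tc3$value[1]))
})

test_that("spectral slope is exact on analytic spectra and scale-invariant", {
  f <- seq(0.25, 120, by = 0.25)
  # flat spectrum: slope exactly 0
  expect_equal(fit_spectral_slope(rep(2, length(f)), f)$slope, 0)
  # linear in linear-log space: recovered to machine precision
  p <- 10^(-0.01 * f)
  fit <- fit_spectral_slope(p, f)
  expect_lt(abs(fit$slope + 0.01), 1e-10)
  expect_lt(fit$residual_rms, 1e-12)
  # global power scaling: slope unchanged, intercept +1
  fit10 <- fit_spectral_slope(10 * p, f)
  expect_equal(fit10$slope, fit$slope)
  expect_equal(fit10$intercept, fit$intercept + 1)
  expect_error(fit_spectral_slope(p - 0.5, f), "positive")
})

test_that("log-log slope fitting recovers the synthetic 1/f exponent", {
  set.seed(32)
  x <- vigilstate:::colored_noise(256 * 120, 256, 2, 20)
  sp <- vigilstate:::epoch_spectra_matrix(x, 256, 4)
  mp <- rowMeans(sp$power)
  fit <- fit_spectral_slope(mp[-1], sp$freq[-1], log_freq = TRUE)
  expect_equal(-fit$slope, 2, tolerance = 0.1)
})

test_that("modulation index behaves at its analytic extremes", {
  set.seed(33)
  ph <- runif(20000, -pi, pi)
  # amplitude independent of phase: MI below sampling noise
  expect_lt(tort_mi(ph, runif(20000)), 0.01)
  # all amplitude mass in one of 18 bins: MI exactly 1
  one_bin <- as.numeric(floor((ph %% (2 * pi)) / (2 * pi) * 18) == 4)
  expect_equal(tort_mi(ph, one_bin), 1.0)
  # MI bounded in [0, 1] and invariant to amplitude scaling
  am <- runif(20000) * (1 + 0.5 * cos(ph))
  m1 <- tort_mi(ph, am)
  expect_gte(m1, 0); expect_lte(m1, 1)
  expect_equal(tort_mi(ph, 100 * am), m1)
})

test_that("modulation index increases with coupling depth", {
  fs <- 256
  set.seed(34)
  mi <- sapply(c(0, 0.3, 0.6, 0.9), function(d)
    modulation_index(coupled_signal(fs, 30, d), fs, c(4, 6), c(50, 70)))
  expect_true(all(diff(mi) > 0))
  expect_error(modulation_index(rnorm(256), 256, c(4, 6), c(100, 130)),
               "Nyquist")
  expect_error(modulation_index(rnorm(256), 256, c(1.5, 2), c(50, 70)),
               "cycles")
})

test_that("comodulogram localises injected coupling and stays near zero on noise", {
  fs <- 256
  set.seed(35)
  t <- (0:(fs * 90 - 1)) / fs
  x <- sin(2 * pi * 2 * t) +
    (1 + 0.9 * cos(2 * pi * 2 * t)) * 0.3 * sin(2 * pi * 40 * t) +
    rnorm(length(t), 0, 0.3)
  cm <- comodulogram(x, fs)
  pk <- which(cm$mi == max(cm$mi), arr.ind = TRUE)[1, ]
  expect_lt(abs(cm$phase_centers[pk[1]] - 2), 1.01)
  expect_lt(abs(cm$amp_centers[pk[2]] - 40), 10.1)
  expect_true(all(cm$mi >= 0 & cm$mi <= 1))
  wn <- comodulogram(rnorm(fs * 90), fs)
  expect_lt(max(wn$mi), 0.02)
  expect_error(comodulogram(rnorm(fs * 30), fs), "60 s")
})
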