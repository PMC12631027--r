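make_calib <- function(antenna, idx) {
  tibble::tibble(antenna_id = antenna, acquisition_index = idx,
                 v_min = -1, v_max = 1,
                 source_wave_ids = replicate(length(idx), character(0),
                                             simplify = FALSE))
}

test_that("nearest calibration picks minimal index distance, earlier on ties", {
  calib <- make_calib("A01", c(0L, 15L, 30L))
  expect_equal(nearest_calibration("A01", 10, calib)$acquisition_index, 15)
  calib2 <- make_calib("A01", c(0L, 14L))
  expect_equal(nearest_calibration("A01", 7, calib2)$acquisition_index, 0)
  expect_error(nearest_calibration("A99", 3, calib), "A99")
})

test_that("min-max normalization is the stated linear map and is invertible", {
  w <- tibble::tibble(
    wave_id = "w1", antenna_id = "A01", acquisition_index = 5L,
    is_calibration = FALSE, samples = list(c(2, 4, 6)))
  calib <- make_calib("A01", 0L)
  calib$v_min <- 0; calib$v_max <- 8
  nw <- normalize_waves(w, calib)
  expect_equal(nw$samples[[1]], c(0.25, 0.5, 0.75))
  back <- denormalize_samples(nw$samples[[1]], 0, 8)
  expect_equal(back, c(2, 4, 6), tolerance = 1e-12)

  calib$v_max <- calib$v_min
  expect_error(calibration_check <- normalize_waves(w, calib), "degenerate")
})

test_that("a calibration wave normalized against its own stats spans [0, 1]", {
  cfg <- det_config(calibration_reps = 1)
  w <- simulate_session(cfg)
  calib <- calibration_stats(w, per_wave = TRUE)
  cal_w <- w[w$is_calibration, ][1, ]
  st <- calib[calib$source_wave_ids |> purrr::map_lgl(~ cal_w$wave_id %in% .x), ]
  nw <- normalize_waves(cal_w, st, keep_calibration = TRUE)
  expect_equal(min(nw$samples[[1]]), 0)
  expect_equal(max(nw$samples[[1]]), 1)
})

test_that("calibration normalization cancels per-antenna gain exactly", {
  # two antennae with gains 0.5 and 2.0, no noise: raw peaks differ,
  # normalized peaks identical (the generative model multiplies the
  # calibration and the experimental response by the same gain)
  base <- det_config()
  w05 <- simulate_session(det_config(seed = 1))
  w <- w05
  gains <- c(A01 = 0.5, A02 = 2.0)
  w$samples <- purrr::map2(w$samples, w$antenna_id, ~ .x * gains[[.y]])

  raw_peaks <- tapply(
    vapply(w$samples[!w$is_calibration & w$odor == "odA"], peak_mag,
           numeric(1)),
    w$antenna_id[!w$is_calibration & w$odor == "odA"], mean)
  expect_gt(stats::var(raw_peaks), 0)

  nw <- normalize_waves(w)
  norm_peaks <- tapply(
    vapply(nw$samples[nw$odor == "odA"], peak_mag, numeric(1)),
    nw$antenna_id[nw$odor == "odA"], mean)
  expect_equal(stats::var(norm_peaks), 0, tolerance = 1e-24)
})

test_that("QC periodogram fraction matches Parseval-based oracles", {
  fs <- 100; n <- 800
  t <- (0:(n - 1)) / fs
  mk <- function(x) {
    w <- tibble::tibble(wave_id = "w", antenna_id = "A", samples = list(x))
    qc_waves(w, sample_rate_hz = fs, allowed_band_hz = c(0, 10),
             threshold = 0.2)
  }
  # pure in-band tone: essentially no out-of-band power
  q1 <- mk(sin(2 * pi * 1 * t))
  expect_lt(q1$out_of_band_power_fraction, 0.01)
  expect_true(q1$qc_pass)

  # in-band tone + equal-RMS out-of-band tone: power splits 50/50
  # (oracle: Parseval, both tones are exact DFT bins at n = 800, fs = 100)
  q2 <- mk(sin(2 * pi * 1 * t) + sin(2 * pi * 30 * t))
  expect_equal(q2$out_of_band_power_fraction, 0.5, tolerance = 1e-6)
  expect_false(q2$qc_pass)

  # all-zero wave is degenerate: fraction 1, failed
  q3 <- mk(rep(0, n))
  expect_equal(q3$out_of_band_power_fraction, 1)
  expect_false(q3$qc_pass)

  # scale invariance
  x <- sin(2 * pi * 1 * t) + 0.3 * sin(2 * pi * 30 * t)
  expect_equal(mk(x)$out_of_band_power_fraction,
               mk(17.3 * x)$out_of_band_power_fraction, tolerance = 1e-12)
})

test_that("QC recovers ground-truth artifact flags on noisy sessions", {
  cfg <- session_config(n_antennae = 6, artifact_rate = 0.3, seed = 19)
  w <- simulate_session(cfg)
  expect_gte(nrow(w), 200)
  q <- qc_waves(normalize_waves(w, keep_calibration = TRUE))
  flagged <- !q$qc_pass
  recall <- sum(flagged & q$artifact) / sum(q$artifact)
  precision <- sum(flagged & q$artifact) / sum(flagged)
  expect_gte(recall, 0.95)
  expect_gte(precision, 0.95)
})

test_that("filter parameter validation matches the gene ranges", {
  expect_error(filter_params(0, 3, 2), "low_cut_hz")
  expect_error(filter_params(0.5, 6, 2), "high_cut_hz")
  expect_error(filter_params(0.5, 3, 5), "order")
  expect_error(filter_params(0.5, 3, 2.5), "order")
  expect_s3_class(filter_params(1, 1.001, 1), "filter_params")
})

test_that("zero-phase Butterworth matches the analytic magnitude oracle", {
  fs <- 100
  params <- filter_params(0.5, 3, order = 2)
  mkw <- function(x) {
    w <- tibble::tibble(wave_id = "w", samples = list(x))
    filter_waves(w, params, sample_rate_hz = fs)$samples[[1]]
  }
  # zero in, zero out
  expect_equal(mkw(rep(0, 1000)), rep(0, 1000))

  # long mid-band sinusoid: steady-state two-pass gain = |H(f)|^2
  f0 <- sqrt(0.5 * 3) # geometric mid-band
  t <- (0:7999) / fs
  y <- mkw(sin(2 * pi * f0 * t))
  interior <- 2000:6000
  gain <- max(abs(y[interior]))
  expect_gte(gain, 0.9)
  expect_lte(gain, 1.0 + 1e-6)
  expect_equal(gain, butterworth_gain(f0, params)^2, tolerance = 0.02)

  # an off-center tone obeys the analytic response too
  y2 <- mkw(sin(2 * pi * 1 * t))
  expect_equal(max(abs(y2[interior])), butterworth_gain(1, params)^2,
               tolerance = 0.02)

  # DC rejection: adding an offset leaves the steady-state interior unchanged
  x <- sin(2 * pi * f0 * t)
  d <- mkw(x + 1) - mkw(x)
  expect_lt(max(abs(d[interior])), 1e-6)

  # linearity: filtering commutes with scaling
  expect_equal(mkw(3.7 * x), 3.7 * mkw(x), tolerance = 1e-9)
})
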