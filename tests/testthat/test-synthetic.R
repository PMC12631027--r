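test_that("session structure yields the expected wave counts", {
  cfg <- tiny_config(odor_templates = list(
    odor_template("cal", 1.0, tau_rise_s = 0.08, tau_decay_s = 0.5),
    odor_template("odA", 0.6, tau_rise_s = 0.06, tau_decay_s = 0.4)),
    calibration_odor = "cal", calibration_reps = 2)
  w <- simulate_session(cfg)
  # 2 antennae x 2 odors x 6 reps experimental; 3 positions x 2 cal waves each
  expect_equal(sum(!w$is_calibration), 24)
  expect_equal(sum(w$is_calibration), 12)
  expect_true(all(lengths(w$samples) == cfg$n_samples))
  # acquisition order strictly increasing within each antenna
  for (a in unique(w$antenna_id)) {
    idx <- w$acquisition_index[w$antenna_id == a]
    expect_true(all(diff(idx) > 0))
  }
  # calibration at first, middle-ish and last acquisition positions
  cal_idx <- w$acquisition_index[w$is_calibration & w$antenna_id == "A01"]
  all_idx <- w$acquisition_index[w$antenna_id == "A01"]
  expect_equal(min(cal_idx), min(all_idx))
  expect_equal(max(cal_idx), max(all_idx))
})

test_that("generation is reproducible and deterministic without noise", {
  w1 <- simulate_session(tiny_config())
  w2 <- simulate_session(tiny_config())
  expect_identical(w1$samples, w2$samples)
  expect_identical(w1$wave_id, w2$wave_id)

  # noise-free, jitter-free, decay-free: repeated deliveries identical
  wd <- simulate_session(det_config())
  for (od in c("odA", "odB")) {
    s <- wd$samples[wd$odor == od & wd$antenna_id == "A01"]
    for (i in seq_along(s)) expect_equal(s[[i]], s[[1]])
  }
})

test_that("noise-free peak magnitudes follow template amplitude order", {
  wd <- simulate_session(det_config())
  mean_peak <- function(od) {
    s <- wd$samples[wd$odor == od & !wd$is_calibration]
    peak_mag(Reduce(`+`, s) / length(s))
  }
  cal <- wd$samples[wd$is_calibration]
  expect_gt(peak_mag(cal[[1]]), mean_peak("odA")) # 1.0 > 0.6
  expect_gt(mean_peak("odA"), mean_peak("odB"))   # 0.6 > 0.3
})

test_that("pre-stimulus segment of noise-free waves is identically zero", {
  cfg <- det_config()
  wd <- simulate_session(cfg)
  n_pre <- round(cfg$pre_s * cfg$sample_rate_hz)
  for (s in wd$samples) expect_identical(s[seq_len(n_pre)], rep(0, n_pre))
})

test_that("responsiveness decay makes calibration peaks decrease over a session", {
  cfg <- det_config(decay_per_trial = 0.02)
  wd <- simulate_session(cfg)
  cal <- wd[wd$is_calibration & wd$antenna_id == "A01", ]
  by_delivery <- split(cal, cal$delivery_id)
  peaks <- vapply(by_delivery, function(d) {
    peak_mag(Reduce(`+`, d$samples) / nrow(d))
  }, numeric(1))
  ord <- order(vapply(by_delivery, function(d) min(d$acquisition_index),
                      numeric(1)))
  expect_true(all(diff(peaks[ord]) < 0))

  # noisy case: decreasing in expectation over repeated seeds
  mean_first_last <- vapply(1:20, function(s) {
    w <- simulate_session(tiny_config(decay_per_trial = 0.02, seed = s))
    cal <- w[w$is_calibration & w$antenna_id == "A01", ]
    rng <- range(cal$acquisition_index)
    first <- peak_mag(Reduce(`+`, cal$samples[cal$acquisition_index <= rng[1] + 2]))
    last <- peak_mag(Reduce(`+`, cal$samples[cal$acquisition_index >= rng[2] - 2]))
    c(first, last)
  }, numeric(2))
  expect_gt(mean(mean_first_last[1, ]), mean(mean_first_last[2, ]))
})

test_that("artifact flags match waves carrying the contaminant frequency", {
  cfg <- tiny_config(artifact_rate = 0.5, noise_sd = 0, seed = 11)
  w <- simulate_session(cfg)
  expect_true(any(w$artifact) && any(!w$artifact))
  # noise-free ground truth: exactly the flagged waves have spectral power
  # at the contaminant frequency (checked at the 60 Hz periodogram bin)
  has_60hz <- vapply(w$samples, function(x) {
    x <- x - mean(x)
    p <- Mod(stats::fft(x))^2
    f <- (seq_along(p) - 1) * cfg$sample_rate_hz / length(p)
    sum(p[abs(f - 60) < 0.5]) / sum(p) > 1e-6
  }, logical(1))
  expect_identical(has_60hz, w$artifact)
})

test_that("invalid configurations are rejected with the violated invariant named", {
  expect_error(session_config(n_antennae = 0), "n_antennae")
  expect_error(tiny_config(decay_per_trial = 1), "decay_per_trial")
  expect_error(tiny_config(noise_sd = -1), "noise_sd")
  expect_error(tiny_config(reps_per_odor = 5), "reps_per_odor")
  expect_error(tiny_config(pre_s = 0.2501), "integer")
  expect_error(tiny_config(calibration_odor = "nope"), "calibration_odor")
  expect_error(odor_template("x", amplitude = 0.5, tau_rise_s = 0.5,
                             tau_decay_s = 0.4), "tau_decay_s")
  expect_error(odor_template("x", amplitude = -1), "amplitude")
})

test_that("rendered template peak equals the stated amplitude", {
  t <- seq(0, 5, by = 1e-3)
  for (tp in default_odor_templates()) {
    v <- template_waveform(tp, t)
    expect_equal(max(abs(v)), tp$amplitude, tolerance = 1e-9)
    expect_true(all(v[t < tp$latency_s] == 0))
  }
})

test_that("concentration-response map is normalized, saturating and monotone", {
  expect_identical(concentration_response(0.6, 1, 0.5), 0.6)
  # closed-form supremum: base * (1 + K)
  expect_equal(concentration_response(0.6, 1e9, 0.5), 0.6 * 1.5,
               tolerance = 1e-6)
  cs <- concentration_response(0.6, c(0.01, 0.1, 1, 10, 100), 0.5)
  expect_true(all(diff(cs) > 0))
  expect_error(concentration_response(0.6, -1, 0.5), "> 0")
})
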