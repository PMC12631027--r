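# Small session configurations used across the suite. Short windows and low
# sample rates keep the statistical structure (calibration deliveries, gain,
# decay, low-rank templates) while staying fast.

two_templates <- function() {
  list(
    odor_template("cal", amplitude = 1.0, latency_s = 0.05,
                  tau_rise_s = 0.08, tau_decay_s = 0.5),
    odor_template("odA", amplitude = 0.6, latency_s = 0.05,
                  tau_rise_s = 0.06, tau_decay_s = 0.4),
    odor_template("odB", amplitude = 0.3, latency_s = 0.12,
                  tau_rise_s = 0.12, tau_decay_s = 0.6)
  )
}

tiny_config <- function(...) {
  args <- list(
    n_antennae = 2,
    odor_templates = two_templates(),
    calibration_odor = "cal",
    reps_per_odor = 6,
    responses_per_delivery = 3,
    sample_rate_hz = 200,
    pre_s = 0.25, post_s = 1.75,
    seed = 42L)
  over <- list(...)
  args[names(over)] <- over
  do.call(session_config, args)
}

# deterministic tiny session: no randomness anywhere
det_config <- function(...) {
  args <- list(antenna_gain_sd = 0, response_jitter_sd = 0,
               decay_per_trial = 0, noise_sd = 0, artifact_rate = 0)
  over <- list(...)
  args[names(over)] <- over
  do.call(tiny_config, args)
}

# waves whose classes differ only through a 1.5 Hz component, on a common
# low-frequency background; used by the GA-vs-grid oracle tests
ga_testbed <- function(n_per_class = 10, fs = 100, dur = 4, seed = 7) {
  set.seed(seed)
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  base <- 0.5 * sin(2 * pi * 0.3 * t)
  rows <- list()
  for (i in seq_len(2 * n_per_class)) {
    cls <- if (i <= n_per_class) "A" else "B"
    v <- base + stats::rnorm(length(t), 0, 0.05)
    if (cls == "B") v <- v + 0.4 * sin(2 * pi * 1.5 * t + stats::runif(1, 0, 2 * pi))
    rows[[i]] <- tibble::tibble(
      wave_id = sprintf("w%03d", i),
      antenna_id = sprintf("A%02d", ((i - 1) %% 4) + 1),
      odor = cls, acquisition_index = i - 1L, samples = list(v))
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "sample_rate_hz") <- fs
  out
}

peak_mag <- function(x) max(abs(x))
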