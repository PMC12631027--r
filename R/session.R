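#' Configure a synthetic EAG recording session
#'
#' Bundles and validates every parameter of the synthetic session generator.
#' The defaults describe the study design the analysis assumes: 15 antennae,
#' a five-odor floral panel with ylang-ylang as the calibration reference,
#' two deliveries of three successive responses per odor (six waves per odor
#' per antenna), calibration deliveries at the beginning, middle and end of
#' each antenna's session, a 5 s analysis window (250 ms pre-stimulus,
#' 4750 ms post) sampled at 1 kHz, multiplicative per-antenna gain
#' variability, and a slow geometric loss of responsiveness over the session.
#'
#' @param n_antennae Number of antennae (sessions) to simulate.
#' @param odor_templates Named list of [odor_template()] objects; every
#'   template is delivered as an experimental odor. Must include
#'   `calibration_odor`.
#' @param calibration_odor Name of the reference odor recorded at the
#'   beginning, middle and end of each antenna session and used for
#'   normalization.
#' @param dilutions Named numeric vector mapping dilution labels to relative
#'   concentration scalars (1 = the reference concentration).
#' @param reps_per_odor Responses per odor x dilution per antenna; must be a
#'   multiple of `responses_per_delivery`.
#' @param responses_per_delivery Successive responses acquired per stimulus
#'   delivery (the valve is reopened every 30 s).
#' @param calibration_reps Calibration waves recorded at each of the three
#'   calibration positions.
#' @param sample_rate_hz Sampling rate, Hz.
#' @param pre_s,post_s Analysis window before/after stimulus onset, seconds;
#'   `sample_rate_hz * (pre_s + post_s)` must be an integer.
#' @param antenna_gain_sd Log-scale standard deviation of the lognormal
#'   per-antenna gain (0 disables gain variability).
#' @param response_jitter_sd Log-scale standard deviation of lognormal
#'   trial-to-trial amplitude jitter applied per wave.
#' @param decay_per_trial Multiplicative responsiveness loss per acquisition
#'   step, in `[0, 1)`.
#' @param noise_sd Standard deviation of additive Gaussian recording noise.
#' @param artifact_rate Probability that a wave carries an out-of-band
#'   contaminant (a fixed-frequency sinusoid), flagged in the ground truth.
#' @param artifact_hz Contaminant frequency, Hz (default mains, 60 Hz).
#' @param artifact_amplitude Contaminant sinusoid amplitude.
#' @param half_saturation Half-saturation constant of the concentration-
#'   response map; see [concentration_response()].
#' @param saturation_ceiling Soft ceiling (normalized voltage units) of the
#'   recording chain; signals are compressed through
#'   `ceiling * tanh(v / ceiling)`. `Inf` (default) disables saturation.
#' @param seed Integer seed; the generated session is fully reproducible
#'   from it.
#'
#' @return An object of class `session_config`.
#' @export
session_config <- function(n_antennae = 15,
                           odor_templates = default_odor_templates(),
                           calibration_odor = "ylang-ylang",
                           dilutions = c("1:1k" = 1),
                           reps_per_odor = 6,
                           responses_per_delivery = 3,
                           calibration_reps = responses_per_delivery,
                           sample_rate_hz = 1000,
                           pre_s = 0.25,
                           post_s = 4.75,
                           antenna_gain_sd = 0.3,
                           response_jitter_sd = 0.1,
                           decay_per_trial = 0.003,
                           noise_sd = 0.02,
                           artifact_rate = 0,
                           artifact_hz = 60,
                           artifact_amplitude = 0.25,
                           half_saturation = 0.5,
                           saturation_ceiling = Inf,
                           seed = 1L) {
  fail <- function(...) stop("invalid session_config: ", ..., call. = FALSE)
  if (n_antennae < 1) fail("`n_antennae` must be >= 1")
  if (!length(odor_templates)) fail("`odor_templates` must be nonempty")
  if (!all(vapply(odor_templates, inherits, logical(1), "odor_template"))) {
    fail("`odor_templates` must all be odor_template objects")
  }
  names(odor_templates) <- vapply(odor_templates, `[[`, character(1), "name")
  if (!calibration_odor %in% names(odor_templates)) {
    fail("`calibration_odor` ('", calibration_odor,
         "') has no template in `odor_templates`")
  }
  if (!length(setdiff(names(odor_templates), character(0)))) fail("no odors")
  if (is.null(names(dilutions)) || any(!nzchar(names(dilutions)))) {
    fail("`dilutions` must be a named numeric vector")
  }
  if (any(dilutions <= 0)) fail("`dilutions` scalars must be > 0")
  if (reps_per_odor < 1 || reps_per_odor %% responses_per_delivery != 0) {
    fail("`reps_per_odor` must be a positive multiple of `responses_per_delivery`")
  }
  n_samples <- sample_rate_hz * (pre_s + post_s)
  if (abs(n_samples - round(n_samples)) > 1e-9) {
    fail("`sample_rate_hz * (pre_s + post_s)` must be an integer number of samples")
  }
  if (decay_per_trial < 0 || decay_per_trial >= 1) {
    fail("`decay_per_trial` must lie in [0, 1)")
  }
  if (antenna_gain_sd < 0) fail("`antenna_gain_sd` must be >= 0")
  if (response_jitter_sd < 0) fail("`response_jitter_sd` must be >= 0")
  if (noise_sd < 0) fail("`noise_sd` must be >= 0")
  if (artifact_rate < 0 || artifact_rate > 1) fail("`artifact_rate` must lie in [0, 1]")
  if (half_saturation <= 0) fail("`half_saturation` must be > 0")
  if (saturation_ceiling <= 0) fail("`saturation_ceiling` must be > 0")

  structure(
    list(n_antennae = as.integer(n_antennae), odor_templates = odor_templates,
         calibration_odor = calibration_odor, dilutions = dilutions,
         reps_per_odor = as.integer(reps_per_odor),
         responses_per_delivery = as.integer(responses_per_delivery),
         calibration_reps = as.integer(calibration_reps),
         sample_rate_hz = sample_rate_hz, pre_s = pre_s, post_s = post_s,
         n_samples = as.integer(round(n_samples)),
         antenna_gain_sd = antenna_gain_sd,
         response_jitter_sd = response_jitter_sd,
         decay_per_trial = decay_per_trial, noise_sd = noise_sd,
         artifact_rate = artifact_rate, artifact_hz = artifact_hz,
         artifact_amplitude = artifact_amplitude,
         half_saturation = half_saturation,
         saturation_ceiling = saturation_ceiling, seed = as.integer(seed)),
    class = "session_config"
  )
}

#' @export
print.session_config <- function(x, ...) {
  cat(sprintf(
    paste0("<session_config> %d antennae, odors: %s (calibration: %s)\n",
           "  %d reps/odor in deliveries of %d; %g Hz, window %g+%g s (%d samples)\n",
           "  gain sd %g, jitter sd %g, decay/trial %g, noise sd %g, artifact rate %g; seed %d\n"),
    x$n_antennae, paste(names(x$odor_templates), collapse = ", "),
    x$calibration_odor, x$reps_per_odor, x$responses_per_delivery,
    x$sample_rate_hz, x$pre_s, x$post_s, x$n_samples,
    x$antenna_gain_sd, x$response_jitter_sd, x$decay_per_trial, x$noise_sd,
    x$artifact_rate, x$seed))
  invisible(x)
}

#' Saturating concentration-response map
#'
#' Maps a relative odor concentration to an effective response amplitude
#' through a hyperbolic (Michaelis-Menten type) saturation,
#' `base * c / (c + K)`, rescaled so that a relative concentration of 1
#' returns `base_amplitude` exactly. Responses are therefore weak at low
#' concentration and approach `base_amplitude * (1 + half_saturation)` as
#' the concentration grows.
#'
#' @param base_amplitude Amplitude at the reference concentration (> 0).
#' @param relative_concentration Concentration relative to the reference
#'   (> 0).
#' @param half_saturation Concentration at which the unscaled response is
#'   half-maximal (> 0).
#' @return Effective amplitude (numeric).
#' @export
#' @examples
#' concentration_response(0.6, 1, 0.5)    # 0.6: the normalization point
#' concentration_response(0.6, 0.01, 0.5) # weak low-end response
concentration_response <- function(base_amplitude, relative_concentration,
                                   half_saturation) {
  if (any(base_amplitude <= 0) || any(relative_concentration <= 0) ||
      any(half_saturation <= 0)) {
    stop("concentration_response arguments must all be > 0", call. = FALSE)
  }
  base_amplitude * relative_concentration * (1 + half_saturation) /
    (relative_concentration + half_saturation)
}

soft_saturate <- function(v, ceiling) {
  if (!is.finite(ceiling)) return(v)
  ceiling * tanh(v / ceiling)
}

#' Generate a labeled synthetic EAG session
#'
#' Simulates the wave table of a full multi-antenna recording session with
#' the statistical structure the downstream analysis assumes. For each
#' antenna, calibration deliveries of the reference odor are recorded at the
#' first, middle and last acquisition positions; every experimental odor x
#' dilution is delivered `reps_per_odor / responses_per_delivery` times in a
#' seeded random order (concentrations ascending within an odor), each
#' delivery yielding `responses_per_delivery` successive waves. Each wave is
#'
#' `gain(antenna) * decay^index * jitter * amplitude(concentration) * template(t - latency)`
#'
#' passed through the optional recording-saturation ceiling, plus Gaussian
#' noise, plus (with probability `artifact_rate`) a fixed-frequency
#' out-of-band sinusoid flagged in the `artifact` column.
#'
#' @param config A [session_config()].
#' @return A tibble with one row per wave: `wave_id`, `antenna_id`, `odor`,
#'   `dilution`, `acquisition_index` (0-based within antenna),
#'   `delivery_id`, `is_calibration`, `artifact` (ground truth), and
#'   `samples` (list-column of numeric vectors of length
#'   `config$n_samples`). The attribute `"config"` carries the generating
#'   configuration.
#' @export
#' @examples
#' waves <- simulate_session(session_config(n_antennae = 2, seed = 7))
#' dplyr::count(waves, odor, is_calibration)
simulate_session <- function(config) {
  stopifnot(inherits(config, "session_config"))
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)

  fs <- config$sample_rate_hz
  t_axis <- (seq_len(config$n_samples) - 1) / fs - config$pre_s
  gains <- stats::rlnorm(config$n_antennae, 0, config$antenna_gain_sd)

  # precompute unit-peak waveforms per odor (template renders at its own
  # amplitude; divide back out so concentration scaling composes cleanly)
  unit_waves <- lapply(config$odor_templates, function(tp) {
    template_waveform(tp, t_axis) / tp$amplitude
  })

  rows <- vector("list", config$n_antennae)
  for (a in seq_len(config$n_antennae)) {
    antenna_id <- sprintf("A%02d", a)
    gain <- gains[[a]]

    exp_grid <- expand.grid(
      odor = names(config$odor_templates),
      dilution = names(config$dilutions),
      rep = seq_len(config$reps_per_odor / config$responses_per_delivery),
      stringsAsFactors = FALSE)
    # randomize odor-block order; ascending concentration within each odor
    odor_order <- sample(names(config$odor_templates))
    dil_rank <- rank(config$dilutions, ties.method = "first")
    exp_grid <- exp_grid[order(match(exp_grid$odor, odor_order),
                               dil_rank[exp_grid$dilution]), , drop = FALSE]

    n_exp <- nrow(exp_grid)
    half <- ceiling(n_exp / 2)
    deliveries <- vector("list", n_exp + 3L)
    # calibration always delivered at the reference concentration
    ref_dil <- names(config$dilutions)[which(config$dilutions == 1)]
    cal <- list(odor = config$calibration_odor,
                dilution = if (length(ref_dil)) ref_dil[[1]] else
                  names(config$dilutions)[[1L]],
                calibration = TRUE)
    di <- 1L
    deliveries[[di]] <- cal; di <- di + 1L
    for (i in seq_len(n_exp)) {
      deliveries[[di]] <- list(odor = exp_grid$odor[[i]],
                               dilution = exp_grid$dilution[[i]],
                               calibration = FALSE)
      di <- di + 1L
      if (i == half) { deliveries[[di]] <- cal; di <- di + 1L }
    }
    deliveries[[di]] <- cal

    acq <- 0L
    wave_rows <- list()
    for (d in seq_along(deliveries)) {
      dl <- deliveries[[d]]
      n_resp <- if (dl$calibration) config$calibration_reps else
        config$responses_per_delivery
      conc <- config$dilutions[[dl$dilution]]
      tp <- config$odor_templates[[dl$odor]]
      eff_amp <- concentration_response(tp$amplitude, conc,
                                        config$half_saturation)
      for (r in seq_len(n_resp)) {
        decay <- (1 - config$decay_per_trial)^acq
        jitter <- if (config$response_jitter_sd > 0) {
          stats::rlnorm(1, 0, config$response_jitter_sd)
        } else 1
        v <- gain * decay * jitter * eff_amp * unit_waves[[dl$odor]]
        v <- soft_saturate(v, config$saturation_ceiling)
        if (config$noise_sd > 0) {
          v <- v + stats::rnorm(config$n_samples, 0, config$noise_sd)
        }
        has_artifact <- config$artifact_rate > 0 &&
          stats::runif(1) < config$artifact_rate
        if (has_artifact) {
          phase <- stats::runif(1, 0, 2 * pi)
          v <- v + config$artifact_amplitude *
            sin(2 * pi * config$artifact_hz * (t_axis + config$pre_s) + phase)
        }
        wave_rows[[length(wave_rows) + 1L]] <- tibble::tibble(
          wave_id = sprintf("%s_w%04d", antenna_id, acq),
          antenna_id = antenna_id,
          odor = dl$odor,
          dilution = dl$dilution,
          acquisition_index = acq,
          delivery_id = sprintf("%s_d%03d", antenna_id, d),
          is_calibration = dl$calibration,
          artifact = has_artifact,
          samples = list(v))
        acq <- acq + 1L
      }
    }
    rows[[a]] <- dplyr::bind_rows(wave_rows)
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "config") <- config
  out
}

#' Sampling metadata of a wave table
#'
#' @param waves A wave tibble as returned by [simulate_session()] or
#'   [read_wave_table()].
#' @return A list with `sample_rate_hz`, `pre_s`, `post_s`, `n_samples`.
#' @export
wave_table_info <- function(waves) {
  cfg <- attr(waves, "config")
  lens <- lengths(waves$samples)
  if (length(unique(lens)) > 1) {
    stop("wave table mixes sample counts: ",
         paste(unique(lens), collapse = ", "), call. = FALSE)
  }
  if (!is.null(cfg)) {
    list(sample_rate_hz = cfg$sample_rate_hz, pre_s = cfg$pre_s,
         post_s = cfg$post_s, n_samples = cfg$n_samples)
  } else {
    list(sample_rate_hz = attr(waves, "sample_rate_hz"),
         pre_s = attr(waves, "pre_s"), post_s = attr(waves, "post_s"),
         n_samples = if (length(lens)) lens[[1]] else 0L)
  }
}
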