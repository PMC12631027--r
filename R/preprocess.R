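#' Summarize calibration deliveries for normalization
#'
#' Collects the reference-odor (calibration) waves of a wave table and
#' computes, per calibration delivery, the minimum and maximum of the
#' delivery's mean wave. Averaging the delivery's successive responses
#' before taking the extrema reduces the influence of recording noise;
#' set `per_wave = TRUE` to compute one set of stats per calibration wave
#' instead.
#'
#' @param waves Wave tibble containing calibration waves
#'   (`is_calibration == TRUE`).
#' @param per_wave If `TRUE`, one stats row per calibration wave rather than
#'   per delivery.
#' @return A tibble of calibration stats: `antenna_id`, `acquisition_index`
#'   (rounded mean index of the contributing waves), `v_min`, `v_max`,
#'   `source_wave_ids` (list-column).
#' @export
calibration_stats <- function(waves, per_wave = FALSE) {
  cal <- dplyr::filter(waves, .data$is_calibration)
  if (nrow(cal) == 0) {
    stop("wave table contains no calibration waves", call. = FALSE)
  }
  key <- if (per_wave || !"delivery_id" %in% names(cal)) {
    cal$wave_id
  } else {
    cal$delivery_id
  }
  out <- cal |>
    dplyr::mutate(.grp = key) |>
    dplyr::group_by(.data$antenna_id, .data$.grp) |>
    dplyr::summarise(
      acquisition_index = as.integer(round(mean(.data$acquisition_index))),
      v_min = min(Reduce(`+`, .data$samples) / dplyr::n()),
      v_max = max(Reduce(`+`, .data$samples) / dplyr::n()),
      source_wave_ids = list(.data$wave_id),
      .groups = "drop") |>
    dplyr::select(-".grp") |>
    dplyr::arrange(.data$antenna_id, .data$acquisition_index)
  bad <- out$v_max <= out$v_min
  if (any(bad)) {
    stop("degenerate (flat) calibration for antenna ",
         out$antenna_id[bad][1], call. = FALSE)
  }
  out
}

#' Pick the calibration nearest in time to a wave
#'
#' Among the same-antenna calibration stats, returns the one whose
#' acquisition index is closest to the wave's; ties go to the earlier
#' calibration.
#'
#' @param antenna_id,acquisition_index Identity and position of the wave.
#' @param calib Calibration stats tibble from [calibration_stats()].
#' @return A one-row tibble of calibration stats.
#' @export
nearest_calibration <- function(antenna_id, acquisition_index, calib) {
  cand <- calib[calib$antenna_id == antenna_id, , drop = FALSE]
  if (nrow(cand) == 0) {
    stop("no calibration available for antenna '", antenna_id, "'",
         call. = FALSE)
  }
  d <- abs(cand$acquisition_index - acquisition_index)
  # ties broken toward the earlier calibration
  cand[order(d, cand$acquisition_index), , drop = FALSE][1, , drop = FALSE]
}

#' Min-max normalize waves against nearest-in-time calibration
#'
#' Rescales every wave by the minimum and maximum of the same antenna's
#' nearest-in-time reference-odor response: `x -> (x - v_min) / (v_max -
#' v_min)`. Because per-antenna gain and slow responsiveness decay multiply
#' the calibration response and the experimental response alike, this
#' proportional rescaling cancels them. Values are deliberately not clipped
#' to `[0, 1]`: a response exceeding the calibration range stays
#' distinguishable.
#'
#' @param waves Wave tibble.
#' @param calib Calibration stats from [calibration_stats()]; computed from
#'   `waves` when omitted.
#' @param keep_calibration Keep the calibration waves (normalized) in the
#'   output? Default drops them, leaving the experimental waves.
#' @return The wave tibble with normalized `samples` and a `calibration_id`
#'   column naming the stats row used.
#' @export
normalize_waves <- function(waves, calib = NULL, keep_calibration = FALSE) {
  if (is.null(calib)) calib <- calibration_stats(waves)
  out <- waves
  cal_used <- character(nrow(waves))
  for (i in seq_len(nrow(waves))) {
    st <- nearest_calibration(waves$antenna_id[[i]],
                              waves$acquisition_index[[i]], calib)
    rng <- st$v_max - st$v_min
    if (rng <= 0) stop("degenerate calibration (v_max == v_min)", call. = FALSE)
    out$samples[[i]] <- (waves$samples[[i]] - st$v_min) / rng
    cal_used[[i]] <- paste0(st$antenna_id, "@", st$acquisition_index)
  }
  out$calibration_id <- cal_used
  if (!keep_calibration && "is_calibration" %in% names(out)) {
    out <- dplyr::filter(out, !.data$is_calibration)
  }
  out
}

#' Invert calibration normalization
#'
#' @param samples Normalized sample vector.
#' @param v_min,v_max Calibration extrema used for normalization.
#' @return The raw-scale sample vector.
#' @export
denormalize_samples <- function(samples, v_min, v_max) {
  samples * (v_max - v_min) + v_min
}

#' Spectral quality control of waves
#'
#' Flags waves contaminated by unexpected frequencies. For each wave the
#' periodogram power spectral density is computed after mean removal and the
#' fraction of total power falling outside the allowed band is compared to a
#' threshold. An all-zero wave is degenerate and fails with fraction 1.
#' The fraction is invariant to rescaling the wave.
#'
#' @param waves Wave tibble.
#' @param sample_rate_hz Sampling rate; taken from the table's metadata when
#'   omitted.
#' @param allowed_band_hz Length-2 numeric `(low, high]` band, Hz, within
#'   `[0, Nyquist]`. Odor-evoked EAG deflections live below ~10 Hz.
#' @param threshold Maximum tolerated out-of-band power fraction.
#' @return `waves` with columns `out_of_band_power_fraction` and `qc_pass`.
#' @export
qc_waves <- function(waves, sample_rate_hz = NULL,
                     allowed_band_hz = c(0, 10), threshold = 0.2) {
  if (is.null(sample_rate_hz)) {
    sample_rate_hz <- wave_table_info(waves)$sample_rate_hz
  }
  lo <- allowed_band_hz[[1]]; hi <- allowed_band_hz[[2]]
  nyq <- sample_rate_hz / 2
  if (!(lo >= 0 && lo < hi && hi <= nyq)) {
    stop("allowed_band_hz must satisfy 0 <= low < high <= Nyquist (",
         nyq, " Hz)", call. = FALSE)
  }
  frac <- vapply(waves$samples, function(x) {
    if (length(x) < 16) stop("QC needs waves of >= 16 samples", call. = FALSE)
    x <- x - mean(x)
    p <- Mod(stats::fft(x))^2
    n <- length(x)
    # one-sided periodogram: frequencies 0 .. Nyquist
    k <- 0:floor(n / 2)
    p <- p[k + 1]
    f <- k * sample_rate_hz / n
    total <- sum(p)
    if (total == 0) return(1) # degenerate all-zero wave
    sum(p[!(f > lo & f <= hi)]) / total
  }, numeric(1))
  waves$out_of_band_power_fraction <- frac
  waves$qc_pass <- frac <= threshold
  attr(waves, "qc") <- list(band_hz = c(lo, hi), threshold = threshold)
  waves
}

#' Butterworth band-pass filter parameters
#'
#' The three-gene chromosome the genetic algorithm tunes: low cut in
#' `(0, 1]` Hz, high cut in `[1.001, 5]` Hz, and filter order 1-4.
#'
#' @param low_cut_hz Low cutoff, Hz.
#' @param high_cut_hz High cutoff, Hz.
#' @param order Filter order (integer 1-4).
#' @return An object of class `filter_params`.
#' @export
filter_params <- function(low_cut_hz = 0.1, high_cut_hz = 4, order = 2) {
  if (!(low_cut_hz > 0 && low_cut_hz <= 1)) {
    stop("`low_cut_hz` must lie in (0, 1]", call. = FALSE)
  }
  if (!(high_cut_hz >= 1.001 && high_cut_hz <= 5)) {
    stop("`high_cut_hz` must lie in [1.001, 5]", call. = FALSE)
  }
  if (low_cut_hz >= high_cut_hz) {
    stop("`low_cut_hz` must be below `high_cut_hz`", call. = FALSE)
  }
  if (order != round(order) || order < 1 || order > 4) {
    stop("`order` must be an integer in 1..4", call. = FALSE)
  }
  structure(list(low_cut_hz = low_cut_hz, high_cut_hz = high_cut_hz,
                 order = as.integer(order)),
            class = "filter_params")
}

#' @export
print.filter_params <- function(x, ...) {
  cat(sprintf("<filter_params> band-pass %.4g-%.4g Hz, order %d\n",
              x$low_cut_hz, x$high_cut_hz, x$order))
  invisible(x)
}

#' Zero-phase Butterworth band-pass filtering
#'
#' Applies the band-pass forward and backward (zero phase, suitable for
#' offline analysis: response latencies are preserved). The effective
#' two-pass magnitude response is `|H(f)|^2`. Output length equals input
#' length; metadata are preserved.
#'
#' @param waves Wave tibble.
#' @param params A [filter_params()].
#' @param sample_rate_hz Sampling rate; from table metadata when omitted.
#' @return `waves` with filtered `samples`.
#' @export
filter_waves <- function(waves, params = filter_params(),
                         sample_rate_hz = NULL) {
  stopifnot(inherits(params, "filter_params"))
  if (is.null(sample_rate_hz)) {
    sample_rate_hz <- wave_table_info(waves)$sample_rate_hz
  }
  nyq <- sample_rate_hz / 2
  if (params$high_cut_hz >= nyq) {
    stop("high cutoff must be below the Nyquist frequency (", nyq, " Hz)",
         call. = FALSE)
  }
  bf <- signal::butter(params$order,
                       c(params$low_cut_hz, params$high_cut_hz) / nyq,
                       type = "pass")
  waves$samples <- lapply(waves$samples, function(x) {
    as.numeric(signal::filtfilt(bf, x))
  })
  attr(waves, "filter_params") <- params
  waves
}

#' Analytic Butterworth band-pass magnitude response
#'
#' Single-pass magnitude `|H(f)|` of the analog-prototype Butterworth
#' band-pass, used as an oracle for the digital filter at frequencies well
#' below Nyquist. The two-pass (zero-phase) gain is its square.
#'
#' @param f_hz Frequencies at which to evaluate, Hz.
#' @param params A [filter_params()].
#' @return Numeric vector of magnitudes in `[0, 1]`.
#' @export
butterworth_gain <- function(f_hz, params) {
  lo <- params$low_cut_hz; hi <- params$high_cut_hz; n <- params$order
  bw <- hi - lo
  f0 <- sqrt(lo * hi)
  # analog band-pass prototype: |H| = 1 / sqrt(1 + ((f^2 - f0^2)/(f*bw))^(2n))
  x <- ifelse(f_hz == 0, Inf, (f_hz^2 - f0^2) / (f_hz * bw))
  1 / sqrt(1 + x^(2 * n))
}
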