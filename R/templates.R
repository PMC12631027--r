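#' Define an odor response template
#'
#' An odor template parameterizes the stereotyped depolarization an odor
#' evokes from an excised antenna: a difference-of-exponentials deflection
#' with an onset latency and an optional positive rebound after recovery.
#' Following standard EAG convention the depolarization is generated as a
#' downward (negative) voltage deflection; the sign is immaterial after
#' min-max calibration normalization.
#'
#' @param name Odor label.
#' @param amplitude Peak deflection magnitude in normalized voltage units
#'   (> 0). The rendered waveform is renormalized so its peak magnitude
#'   equals `amplitude` exactly.
#' @param latency_s Response onset delay after stimulus onset, seconds (>= 0).
#' @param tau_rise_s Rise time constant, seconds (> 0).
#' @param tau_decay_s Decay time constant, seconds; must exceed `tau_rise_s`
#'   so the difference of exponentials is well formed.
#' @param positive_rebound Fraction of `amplitude` contributed by a slow
#'   positive overshoot after the depolarization recovers (>= 0).
#'
#' @return An object of class `odor_template`.
#' @export
#' @examples
#' tpl <- odor_template("limonene", amplitude = 0.3, latency_s = 0.05,
#'                      tau_rise_s = 0.08, tau_decay_s = 0.6)
#' v <- template_waveform(tpl, t = seq(0, 5, by = 1e-3))
#' max(abs(v)) # == 0.3
odor_template <- function(name, amplitude, latency_s = 0.05,
                          tau_rise_s = 0.08, tau_decay_s = 0.6,
                          positive_rebound = 0) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(amplitude) || amplitude <= 0) {
    stop("`amplitude` must be > 0 for odor '", name, "'", call. = FALSE)
  }
  if (latency_s < 0) stop("`latency_s` must be >= 0", call. = FALSE)
  if (tau_rise_s <= 0) stop("`tau_rise_s` must be > 0", call. = FALSE)
  if (tau_decay_s <= tau_rise_s) {
    stop("`tau_decay_s` must exceed `tau_rise_s` (odor '", name, "')",
         call. = FALSE)
  }
  if (positive_rebound < 0) stop("`positive_rebound` must be >= 0", call. = FALSE)
  structure(
    list(name = name, amplitude = amplitude, latency_s = latency_s,
         tau_rise_s = tau_rise_s, tau_decay_s = tau_decay_s,
         positive_rebound = positive_rebound),
    class = "odor_template"
  )
}

#' @export
print.odor_template <- function(x, ...) {
  cat(sprintf(
    "<odor_template> %s: amplitude %.3g, latency %.3g s, tau_rise %.3g s, tau_decay %.3g s, rebound %.3g\n",
    x$name, x$amplitude, x$latency_s, x$tau_rise_s, x$tau_decay_s,
    x$positive_rebound))
  invisible(x)
}

# Raw (unnormalized) difference-of-exponentials shape, zero before onset.
diffexp_shape <- function(t, tau_rise, tau_decay) {
  s <- numeric(length(t))
  on <- t >= 0
  s[on] <- exp(-t[on] / tau_decay) - exp(-t[on] / tau_rise)
  s
}

#' Render an odor template as a voltage waveform
#'
#' Evaluates the template on a time axis where `t = 0` is the stimulus onset.
#' The waveform is identically zero before `latency_s` and its peak magnitude
#' equals the template amplitude after internal renormalization.
#'
#' @param template An [odor_template()].
#' @param t Numeric vector of times in seconds relative to stimulus onset.
#' @return Numeric vector of voltages, same length as `t`.
#' @export
template_waveform <- function(template, t) {
  stopifnot(inherits(template, "odor_template"))
  ts <- t - template$latency_s
  v <- -diffexp_shape(ts, template$tau_rise_s, template$tau_decay_s)
  if (template$positive_rebound > 0) {
    # slow positive overshoot, onset delayed by the depolarization's peak time
    t_peak <- with(template, tau_rise_s * tau_decay_s /
                     (tau_decay_s - tau_rise_s) * log(tau_decay_s / tau_rise_s))
    reb <- diffexp_shape(ts - 2 * t_peak,
                         2 * template$tau_rise_s, 3 * template$tau_decay_s)
    pk_main <- max(abs(v))
    pk_reb <- max(abs(reb))
    if (pk_reb > 0) {
      v <- v + template$positive_rebound * (pk_main / pk_reb) * reb
    }
  }
  pk <- max(abs(v))
  if (pk == 0) return(v) # window ends before onset
  v * (template$amplitude / pk)
}

#' Default odor template panel
#'
#' Five templates patterned on the qualitative ordering of responses the
#' moth antenna gives to a floral panel: the ylang-ylang reference odor
#' evokes the largest response, benzyl alcohol a large response with a
#' pronounced positive rebound, lemon oil and linalool intermediate
#' responses (linalool with a delayed onset), and limonene the smallest.
#'
#' @return A named list of [odor_template()] objects.
#' @export
default_odor_templates <- function() {
  tpls <- list(
    odor_template("ylang-ylang",   amplitude = 1.00, latency_s = 0.05,
                  tau_rise_s = 0.10, tau_decay_s = 0.80, positive_rebound = 0.05),
    odor_template("benzyl-alcohol", amplitude = 0.80, latency_s = 0.06,
                  tau_rise_s = 0.12, tau_decay_s = 1.00, positive_rebound = 0.30),
    odor_template("lemon-oil",     amplitude = 0.70, latency_s = 0.05,
                  tau_rise_s = 0.07, tau_decay_s = 0.55, positive_rebound = 0.05),
    odor_template("linalool",      amplitude = 0.55, latency_s = 0.12,
                  tau_rise_s = 0.15, tau_decay_s = 0.70, positive_rebound = 0),
    odor_template("limonene",      amplitude = 0.30, latency_s = 0.05,
                  tau_rise_s = 0.06, tau_decay_s = 0.45, positive_rebound = 0)
  )
  stats::setNames(tpls, vapply(tpls, `[[`, character(1), "name"))
}
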