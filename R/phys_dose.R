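#' Electroporation exposure specification
#'
#' Describes one nanosecond pulsed electric field (nsEP) exposure: pulse
#' width, field strength (from voltage and electrode gap), pulse count and
#' repetition rate. The default is the screen's standard treatment: a 20-Hz
#' train of 20 pulses of 300 ns at 700 V across a 1-mm cuvette gap (7 kV/cm).
#'
#' @param pulse_width pulse duration in seconds.
#' @param n_pulses number of pulses (>= 0).
#' @param voltage pulse amplitude in volts.
#' @param gap electrode gap in metres.
#' @param rep_rate repetition rate in Hz.
#' @return list of class \code{"exposure_spec"}; includes \code{field} =
#'   voltage/gap in V/m.
#' @export
exposure_spec <- function(pulse_width = 300e-9, n_pulses = 20,
                          voltage = 700, gap = 1e-3, rep_rate = 20) {
  stopifnot(pulse_width > 0, n_pulses >= 0, voltage > 0, gap > 0,
            rep_rate > 0)
  structure(list(pulse_width = pulse_width, n_pulses = n_pulses,
                 voltage = voltage, gap = gap, rep_rate = rep_rate,
                 field = voltage / gap),
            class = "exposure_spec")
}

#' Exposure medium electrical/thermal properties
#'
#' Defaults are typical for a physiological growth medium: conductivity
#' 1.4 S/m and volumetric heat capacity 4.18e6 J m^-3 K^-1 (that of water).
#'
#' @param conductivity electrical conductivity sigma in S/m.
#' @param heat_capacity volumetric heat capacity rho*c in J m^-3 K^-1.
#' @return list of class \code{"medium_props"}.
#' @export
medium_props <- function(conductivity = 1.4, heat_capacity = 4.18e6) {
  stopifnot(conductivity > 0, heat_capacity > 0)
  structure(list(conductivity = conductivity, heat_capacity = heat_capacity),
            class = "medium_props")
}

#' Adiabatic heating bound for a pulse train
#'
#' Maximum temperature rise disregarding heat dissipation:
#' \deqn{\Delta T = \sigma E^2 \tau N / (\rho c)}
#' with conductivity \eqn{\sigma}, field \eqn{E}, pulse width \eqn{\tau},
#' pulse count \eqn{N} and volumetric heat capacity \eqn{\rho c}. Strictly
#' linear in the pulse count. For the standard 20-pulse, 300-ns, 7 kV/cm
#' treatment in growth medium the rise stays below 1 K (2 K at 40 pulses).
#'
#' @param exposure an \code{\link{exposure_spec}}.
#' @param medium a \code{\link{medium_props}}.
#' @return temperature rise in kelvin.
#' @export
adiabatic_heating <- function(exposure = exposure_spec(),
                              medium = medium_props()) {
  stopifnot(inherits(exposure, "exposure_spec"),
            inherits(medium, "medium_props"))
  medium$conductivity * exposure$field^2 * exposure$pulse_width *
    exposure$n_pulses / medium$heat_capacity
}

#' Linear dose-response fit with divergence detection
#'
#' Fits ordinary least squares to mean sham-corrected uptake versus pulse
#' number for doses at or below \code{limit}, returns the 95\% confidence
#' band of the fit, and flags above-limit points lying outside the
#' extrapolated 95\% prediction band as "diverged" (each flagged point is a
#' single measured value, so the prediction band is the appropriate
#' reference). Divergence above ~50 pulses marks the onset of secondary
#' effects (cell swelling, membrane rupture) that obscure permeabilization.
#'
#' @param pulses numeric vector of pulse counts.
#' @param delta_f numeric vector of mean ΔF values (same length).
#' @param limit dose up to which the response is treated as linear
#'   (default 50 pulses).
#' @param level band confidence level (default 0.95).
#' @return list with \code{slope}, \code{intercept}, \code{fit} (the
#'   \code{lm} object), \code{band} (data.frame: pulses, fit, ci_lwr, ci_upr,
#'   pi_lwr, pi_upr for every input dose) and \code{diverged} (data.frame of
#'   above-limit points with a logical \code{diverged} flag).
#' @export
fit_dose_response <- function(pulses, delta_f, limit = 50, level = 0.95) {
  stopifnot(length(pulses) == length(delta_f))
  in_range <- pulses <= limit
  if (sum(in_range) < 3)
    stop("need at least 3 points at or below the linear limit")
  d <- data.frame(pulses = pulses, delta_f = delta_f)
  fit <- stats::lm(delta_f ~ pulses, data = d[in_range, ])
  ci <- stats::predict(fit, newdata = d, interval = "confidence",
                       level = level)
  pi <- stats::predict(fit, newdata = d, interval = "prediction",
                       level = level)
  band <- data.frame(pulses = pulses, fit = ci[, "fit"],
                     ci_lwr = ci[, "lwr"], ci_upr = ci[, "upr"],
                     pi_lwr = pi[, "lwr"], pi_upr = pi[, "upr"])
  above <- d[!in_range, , drop = FALSE]
  diverged <- data.frame(above,
                         diverged = delta_f[!in_range] < pi[!in_range, "lwr"] |
                           delta_f[!in_range] > pi[!in_range, "upr"])
  rownames(diverged) <- NULL
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       fit = fit, band = band, diverged = diverged)
}
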