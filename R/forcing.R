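# Asymmetric 24 h circadian forcing of CRH production.

#' Parameters of the circadian forcing function
#'
#' The circadian drive is the asymmetric, strictly positive, 1440-min
#' periodic function
#' \deqn{D(t) = d_1 - 0.079145093\, d_2 + \{0.064 \sin(2\pi(t-840)/1440) +
#'   0.12\,|\sin(\pi(t-840)/1440)|\}\, d_2}
#' with `t` in minutes since 00:00 of day 1, so the phase of 840 min places
#' the reference point at 14:00. `D` multiplies the CRH production constant
#' `k2` (step R2), making CRH inflow a periodic function of clock time.
#'
#' @param d1,d2 Dimensionless shape parameters (defaults 0.2662 and 2.5).
#' @param offset_coefficient Constant multiplying `d2` in the offset term.
#' @param sine_amplitude Amplitude of the full-period sine term.
#' @param rectified_amplitude Amplitude of the rectified (absolute-value)
#'   half-period sine term; the rectification is what makes `D` asymmetric.
#' @param phase_minutes Phase shift in minutes (840 = 14:00).
#' @param period_minutes Period in minutes (1440 = 24 h).
#' @return A list of class `forcing_params`.
#' @export
forcing_params <- function(d1 = 0.2662, d2 = 2.5,
                           offset_coefficient = 0.079145093,
                           sine_amplitude = 0.064,
                           rectified_amplitude = 0.12,
                           phase_minutes = 840, period_minutes = 1440) {
  stopifnot(period_minutes > 0)
  structure(list(d1 = d1, d2 = d2,
                 offset_coefficient = offset_coefficient,
                 sine_amplitude = sine_amplitude,
                 rectified_amplitude = rectified_amplitude,
                 phase_minutes = phase_minutes,
                 period_minutes = period_minutes),
            class = "forcing_params")
}

#' Evaluate the circadian drive D(t)
#'
#' Vectorised over `t`; defined for all real `t` and periodic with period
#' `period_minutes`. With default parameters D is strictly positive
#' (minimum about 0.066 near t = 747 min) and bounded above by 1.
#'
#' @param t Time(s) in minutes since 00:00 of day 1.
#' @param params A [forcing_params()] object.
#' @return Dimensionless drive value(s).
#' @export
circadian_drive <- function(t, params = forcing_params()) {
  stopifnot(inherits(params, "forcing_params"))
  p <- params
  x <- (t - p$phase_minutes) / p$period_minutes
  p$d1 - p$offset_coefficient * p$d2 +
    (p$sine_amplitude * sin(2 * pi * x) +
     p$rectified_amplitude * abs(sin(pi * x))) * p$d2
}

#' Mean of D over one period
#'
#' Average of the circadian drive over a 1-min grid spanning one period;
#' used as the frozen forcing value for fixed-point analysis.
#'
#' @param params A [forcing_params()] object.
#' @return Scalar mean drive.
#' @export
mean_circadian_drive <- function(params = forcing_params()) {
  mean(circadian_drive(seq(0, params$period_minutes - 1), params))
}

#' Tabulate D over one period
#'
#' @param params A [forcing_params()] object.
#' @param dt Grid spacing in minutes.
#' @return data.frame with `time_min`, `clock` and `drive`.
#' @export
circadian_drive_table <- function(params = forcing_params(), dt = 1) {
  t <- seq(0, params$period_minutes, by = dt)
  data.frame(time_min = t, clock = minutes_to_clock(t),
             drive = circadian_drive(t, params))
}
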