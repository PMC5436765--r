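# Ultradian/circadian oscillation analytics and unit/dose calculators.

# Resample a (time, value) series onto a regular grid. Trajectories carry
# extra rows at pulse times, so metrics always work on an evenly spaced
# interpolant.
resample_series <- function(time, value, dt = 1) {
  grid <- seq(min(time), max(time), by = dt)
  list(time = grid,
       value = stats::approx(time, value, xout = grid, ties = "ordered",
                             rule = 2)$y,
       dt = dt)
}

#' Local maxima filtered by topographic prominence
#'
#' A point is a peak if it is a strict local maximum; its prominence is its
#' height minus the higher of the two lowest points one must descend to on
#' either side before reaching higher ground (or the series boundary).
#' Peaks with prominence below `min_prominence` are discarded. The
#' threshold is relative to the data, so detection is invariant to uniform
#' scaling of the series.
#'
#' @param x Numeric series.
#' @param min_prominence Minimum prominence, in the units of `x`.
#' @return Integer indices of retained peaks.
#' @export
find_peaks <- function(x, min_prominence = 0) {
  n <- length(x)
  if (n < 3) return(integer(0))
  d <- diff(x)
  cand <- which(d[-length(d)] > 0 & d[-1] <= 0) + 1L
  cand <- cand[x[cand] > x[pmax(cand - 1L, 1L)]]
  if (!length(cand)) return(integer(0))
  prom <- vapply(cand, function(i) {
    h <- x[i]
    left <- if (i > 1) x[seq_len(i - 1L)] else numeric(0)
    hi <- which(left >= h)
    lmin <- if (length(hi)) min(left[seq.int(max(hi), i - 1L)])
            else min(left, h)
    right <- if (i < n) x[seq.int(i + 1L, n)] else numeric(0)
    hi <- which(right >= h)
    rmin <- if (length(hi)) min(right[seq_len(min(hi))])
            else min(right, h)
    h - max(lmin, rmin)
  }, numeric(1))
  cand[prom >= min_prominence]
}

#' Remove the circadian baseline from a series
#'
#' Subtracts a running median whose window (default 6 h) is much longer
#' than the ultradian period but shorter than a day, leaving the ultradian
#' pulsatility around zero.
#'
#' @param value Numeric series on a regular grid.
#' @param dt Grid spacing (min).
#' @param window_min Detrending window length (min).
#' @return Detrended series.
#' @export
detrend_series <- function(value, dt = 1, window_min = 360) {
  kk <- max(3L, round(window_min / dt))
  if (kk %% 2 == 0) kk <- kk + 1L
  kk <- min(kk, if (length(value) %% 2) length(value)
                else length(value) - 1L)
  value - stats::runmed(value, kk)
}

#' Ultradian oscillation metrics of a corticosterone series
#'
#' Works on the circadian-detrended series (running-median window
#' `detrend_window_min`); peaks and troughs are local extrema with
#' prominence at least `prominence_frac` times the interquartile range of
#' the detrended window. Reported metrics:
#' \itemize{
#'   \item `ultradian_period_min`: median inter-peak interval;
#'   \item `ultradian_frequency_per_day`: detected peaks per 24 h of
#'     window;
#'   \item `ultradian_amplitude_M`: median peak-minus-following-trough
#'     drop, measured on the raw (untrended) series;
#'   \item `largest_amplitude_bounds_M`: the highest detected peak and
#'     lowest detected trough in the window -- the extreme excursions of
#'     the largest oscillation, which by construction bracket every
#'     detected extremum;
#'   \item `circadian_modulation_index`: (max - min)/(max + min) of the
#'     hourly maxima of the raw series -- the daily upper envelope; near 1
#'     for a strongly circadian-gated pattern, near 0 when circadian
#'     structure is lost;
#'   \item `daily_mean_M`: mean per complete 1440-min day in the window.
#' }
#' With fewer than 2 detected peaks the oscillation metrics are `NA` and
#' `oscillations_present` is `FALSE`.
#'
#' @param x An `hpa_trajectory` (its CTS series is used) or a data.frame
#'   with columns `time` (min) and `value`.
#' @param window Optional `c(t_min, t_max)` analysis window (minutes); it
#'   should exclude the transient first day.
#' @param detrend_window_min Running-median window (min, default 360).
#' @param prominence_frac Prominence threshold as a fraction of the
#'   detrended interquartile range (default 0.05).
#' @param species Species to analyse when `x` is a trajectory.
#' @return List of class `oscillation_metrics`.
#' @export
detect_ultradian <- function(x, window = NULL, detrend_window_min = 360,
                             prominence_frac = 0.05, species = "CTS") {
  ser <- if (inherits(x, "hpa_trajectory"))
    trajectory_series(x, species, window)
  else {
    stopifnot(is.data.frame(x), all(c("time", "value") %in% names(x)))
    if (is.null(window)) x
    else x[x$time >= window[1] & x$time <= window[2], ]
  }
  rs <- resample_series(ser$time, ser$value)
  det <- detrend_series(rs$value, rs$dt, detrend_window_min)
  thr <- prominence_frac * stats::IQR(det)
  pk <- find_peaks(det, thr)
  tr <- find_peaks(-det, thr)
  span_days <- (max(rs$time) - min(rs$time)) / 1440

  hours <- floor(rs$time / 60)
  hourly_max <- tapply(rs$value, hours, max)
  cmi <- (max(hourly_max) - min(hourly_max)) /
         (max(hourly_max) + min(hourly_max))
  day_id <- floor(rs$time / 1440)
  full <- names(which(table(day_id) >= 1440 / rs$dt))
  daily_mean <- tapply(rs$value, day_id, mean)[full]

  out <- list(oscillations_present = length(pk) >= 2,
              n_peaks = length(pk),
              ultradian_period_min = NA_real_,
              ultradian_frequency_per_day = NA_real_,
              ultradian_amplitude_M = NA_real_,
              largest_amplitude_bounds_M = c(peak = NA_real_,
                                             trough = NA_real_),
              circadian_modulation_index = unname(cmi),
              daily_mean_M = daily_mean,
              peak_times = rs$time[pk], trough_times = rs$time[tr],
              window = c(min(rs$time), max(rs$time)))
  if (length(pk) >= 2) {
    out$ultradian_period_min <- stats::median(diff(rs$time[pk]))
    out$ultradian_frequency_per_day <- length(pk) / span_days
    amp <- rep(NA_real_, length(pk)); bounds <- NULL
    for (i in seq_along(pk)) {
      nxt <- tr[tr > pk[i]]
      if (length(nxt))
        amp[i] <- rs$value[pk[i]] - rs$value[nxt[1]]
    }
    if (any(!is.na(amp)))
      out$ultradian_amplitude_M <- stats::median(amp, na.rm = TRUE)
    if (length(tr))
      out$largest_amplitude_bounds_M <- c(peak = max(rs$value[pk]),
                                          trough = min(rs$value[tr]))
  }
  class(out) <- "oscillation_metrics"
  out
}

#' @export
print.oscillation_metrics <- function(x, ...) {
  if (!x$oscillations_present) {
    cat("No ultradian oscillations detected (<2 peaks)\n")
    return(invisible(x))
  }
  cat(sprintf(paste0(
    "Ultradian: %d peaks, median period %.1f min, %.1f peaks/day,\n",
    "  median amplitude %.3e M; largest oscillation peak %.3e / trough",
    " %.3e M\n  circadian modulation index %.3f\n"),
    x$n_peaks, x$ultradian_period_min, x$ultradian_frequency_per_day,
    x$ultradian_amplitude_M, x$largest_amplitude_bounds_M[["peak"]],
    x$largest_amplitude_bounds_M[["trough"]],
    x$circadian_modulation_index))
  invisible(x)
}

#' Circadian period by autocorrelation
#'
#' Lag (hours) of the autocorrelation maximum of the series, searched over
#' lags 18--30 h. The series must span at least four full days (after
#' discarding the transient).
#'
#' @param x An `hpa_trajectory` or data.frame with `time`, `value`.
#' @param window Optional analysis window (minutes).
#' @param lag_range_h Search range in hours.
#' @param species Species when `x` is a trajectory.
#' @return Period estimate in hours.
#' @export
circadian_period_estimate <- function(x, window = NULL,
                                      lag_range_h = c(18, 30),
                                      species = "CTS") {
  ser <- if (inherits(x, "hpa_trajectory"))
    trajectory_series(x, species, window)
  else {
    if (!is.null(window)) x <- x[x$time >= window[1] & x$time <= window[2], ]
    x
  }
  rs <- resample_series(ser$time, ser$value)
  span <- max(rs$time) - min(rs$time)
  if (span < 4 * 1440)
    stop("series spans ", round(span / 1440, 2),
         " days; >= 4 full days required")
  lags <- round(lag_range_h * 60 / rs$dt)
  ac <- stats::acf(rs$value, lag.max = lags[2], plot = FALSE,
                   demean = TRUE)$acf[-1]
  sub <- seq.int(lags[1], lags[2])
  best <- sub[which.max(ac[sub])]
  best * rs$dt / 60
}

#' Molar concentration to assay units
#'
#' ng/mL = M x molar mass (g/mol) x 1e6 (since M x g/mol = g/L =
#' 1e6 ng / 1e3 mL).
#'
#' @param concentration Molar concentration(s), >= 0.
#' @param molar_mass Molar mass in g/mol (corticosterone: 346.46).
#' @return Concentration in ng/mL.
#' @export
molar_to_ng_per_ml <- function(concentration, molar_mass = 346.46) {
  if (any(concentration < 0) || molar_mass <= 0)
    stop("inputs must be nonnegative (molar_mass > 0)")
  concentration * molar_mass * 1e6
}

#' @rdname molar_to_ng_per_ml
#' @param ng_per_ml Concentration(s) in ng/mL, >= 0.
#' @export
ng_per_ml_to_molar <- function(ng_per_ml, molar_mass = 346.46) {
  if (any(ng_per_ml < 0) || molar_mass <= 0)
    stop("inputs must be nonnegative (molar_mass > 0)")
  ng_per_ml / molar_mass / 1e6
}

#' Peripheral concentration reached in a CRH stimulation test
#'
#' Converts an intravenous CRH dose to the resulting blood concentration.
#' Two blood-volume conventions are supported: a total volume in litres
#' (requires the body mass, dose being per kg), or a per-kg volume in
#' mL/kg (mass cancels). Rat/human CRH is a 41-residue peptide of molar
#' mass ~4758 g/mol.
#'
#' @param dose_ug_per_kg Dose in micrograms per kg body mass.
#' @param blood_volume_l Total blood volume in litres (with
#'   `body_mass_kg`).
#' @param body_mass_kg Body mass in kg (with `blood_volume_l`).
#' @param blood_ml_per_kg Blood volume per kg body mass, mL/kg.
#' @param molar_mass Molar mass of the injected peptide (g/mol).
#' @return Concentration in M.
#' @examples
#' # rat: 10 ug/kg into ~70 mL/kg blood -> ~3e-8 M
#' stimulation_test_concentration(10, blood_ml_per_kg = 70)
#' # human: 1 ug/kg, 70 kg, 5.25 L blood -> ~3e-9 M
#' stimulation_test_concentration(1, blood_volume_l = 5.25,
#'                                body_mass_kg = 70)
#' @export
stimulation_test_concentration <- function(dose_ug_per_kg,
                                           blood_volume_l = NULL,
                                           body_mass_kg = NULL,
                                           blood_ml_per_kg = NULL,
                                           molar_mass = 4758) {
  if (dose_ug_per_kg < 0) stop("dose must be >= 0")
  per_kg <- !is.null(blood_ml_per_kg)
  total <- !is.null(blood_volume_l)
  if (per_kg == total)
    stop("give exactly one of blood_ml_per_kg or blood_volume_l")
  if (per_kg) {
    if (blood_ml_per_kg <= 0) stop("blood volume must be > 0")
    grams_per_l <- dose_ug_per_kg * 1e-6 / (blood_ml_per_kg * 1e-3)
  } else {
    if (is.null(body_mass_kg))
      stop("a total blood volume needs body_mass_kg to resolve the",
           " per-kg dose")
    if (blood_volume_l <= 0 || body_mass_kg <= 0)
      stop("blood volume and body mass must be > 0")
    grams_per_l <- dose_ug_per_kg * body_mass_kg * 1e-6 / blood_volume_l
  }
  grams_per_l / molar_mass
}
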