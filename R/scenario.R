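# Scenario configuration: conditions, pulse schedules, clock-time helpers.

#' Clock-time helpers
#'
#' Convert between "HH:MM" clock labels and minutes since 00:00 of day 1.
#' `clock_to_minutes("21:12", day = 2)` is 2712; `minutes_to_clock` wraps
#' modulo 24 h and is vectorised.
#'
#' @param clock Character "HH:MM".
#' @param day Simulation day (1-based).
#' @param t Minutes since 00:00 of day 1.
#' @return Minutes, or character clock label(s).
#' @export
clock_to_minutes <- function(clock, day = 1) {
  m <- regmatches(clock, regexec("^([0-9]{1,2}):([0-9]{2})$", clock))[[1]]
  if (length(m) != 3) stop("invalid clock time: ", clock)
  hh <- as.integer(m[2]); mm <- as.integer(m[3])
  if (hh > 23 || mm > 59) stop("invalid clock time: ", clock)
  (day - 1) * 1440 + hh * 60 + mm
}

#' @rdname clock_to_minutes
#' @export
minutes_to_clock <- function(t) {
  tm <- round(t) %% 1440
  sprintf("%02d:%02d", tm %/% 60, tm %% 60)
}

#' Timed additive perturbation schedule
#'
#' An ordered sequence of instantaneous concentration increments: at each
#' event time the integration is stopped, the named species is incremented,
#' and integration restarts from the perturbed state.
#'
#' @param times Event times in minutes, strictly increasing.
#' @param species Perturbed species (recycled), each one of [hpa_species()].
#' @param increments Nonnegative molar increments (recycled).
#' @return A data.frame of class `perturbation_schedule` with columns
#'   `time`, `species`, `increment`.
#' @export
perturbation_schedule <- function(times = numeric(),
                                  species = character(),
                                  increments = numeric()) {
  if (length(times) == 0) {
    out <- data.frame(time = numeric(), species = character(),
                      increment = numeric(), stringsAsFactors = FALSE)
    class(out) <- c("perturbation_schedule", "data.frame")
    return(out)
  }
  species <- rep_len(as.character(species), length(times))
  increments <- rep_len(as.numeric(increments), length(times))
  if (any(diff(times) <= 0)) stop("event times must be strictly increasing")
  if (any(increments < 0)) stop("increments must be >= 0")
  if (any(!species %in% hpa_species()))
    stop("unknown species: ",
         paste(unique(setdiff(species, hpa_species())), collapse = ", "))
  out <- data.frame(time = as.numeric(times), species = species,
                    increment = increments, stringsAsFactors = FALSE)
  class(out) <- c("perturbation_schedule", "data.frame")
  out
}

#' Kindling pulse schedule
#'
#' The LHK protocol as a pulse train: a first additive CRH pulse at
#' `start`, then one every `pulse_interval_s` seconds, with no pulse at or
#' after `start + duration_min`. With the defaults (40 s interval, 50 min
#' duration) this gives 75 pulses, the last at `start` + 49 min 20 s, so
#' the train spans the 50-min kindling window.
#'
#' @param start Start time in minutes (e.g.
#'   `clock_to_minutes("21:12", day = 2)`).
#' @param pulse_interval_s Seconds between pulses (default 40).
#' @param duration_min Length of the kindling window in minutes
#'   (default 50).
#' @param intensity Molar CRH increment per pulse (default 5e-8).
#' @param species Perturbed species (default "CRH").
#' @return A [perturbation_schedule()].
#' @export
kindling_schedule <- function(start, pulse_interval_s = 40,
                              duration_min = 50, intensity = 5e-8,
                              species = "CRH") {
  stopifnot(pulse_interval_s > 0, duration_min >= 0)
  n <- ceiling(duration_min * 60 / pulse_interval_s)
  if (n <= 0) return(perturbation_schedule())
  times <- start + (seq_len(n) - 1) * pulse_interval_s / 60
  times <- times[times < start + duration_min]
  perturbation_schedule(times, species, intensity)
}

#' Apply one instantaneous pulse to a state
#'
#' Increases the target species by exactly `increment`; all other entries
#' are returned bit-identical.
#'
#' @param state Named concentration vector.
#' @param species One of [hpa_species()].
#' @param increment Nonnegative molar increment.
#' @return The perturbed state vector.
#' @export
apply_pulse <- function(state, species, increment) {
  if (!species %in% names(state)) stop("unknown species: ", species)
  if (increment < 0) stop("increment must be >= 0")
  state[[species]] <- state[[species]] + increment
  state
}

#' Solver tolerance presets
#'
#' `strict` is the published pair (absolute 3e-20, relative 1e-14), used to
#' rule out numerical artefacts. `relaxed` is the published robustness pair
#' (1e-9, 3e-6), reported to give the same dynamical behaviour. `standard`
#' (1e-15, 1e-8) is this package's working preset for long batch runs: its
#' absolute tolerance sits below the smallest species scale (CRH and ACTH
#' are ~1e-12 M) so trajectories stay positive, at a fraction of the strict
#' cost.
#'
#' @param preset One of "strict", "standard", "relaxed".
#' @return List with `atol` and `rtol`.
#' @export
solver_tolerances <- function(preset = c("strict", "standard", "relaxed")) {
  switch(match.arg(preset),
         strict   = list(atol = 3e-20, rtol = 1e-14),
         standard = list(atol = 1e-15, rtol = 1e-8),
         relaxed  = list(atol = 1e-9,  rtol = 3e-6))
}

#' Configure a simulation scenario
#'
#' Bundles everything one integration needs: the condition preset, the
#' stress multiplier on the circadian-forced CRH production step, an
#' optional pulse schedule, the initial state, the time span, and stiff
#' solver options.
#'
#' Presets: `control` leaves `k2` unscaled; `sham` multiplies `k2` by
#' 1.1765 (surgery/handling potentiation); `lhk` uses the sham multiplier
#' for the whole span plus a default 50-min kindling train of 5e-8 M CRH
#' pulses starting 21:12 on day 2. `custom` applies whatever is passed.
#'
#' @param condition One of "control", "sham", "lhk", "custom".
#' @param k2_multiplier Dimensionless multiplier on `k2`; defaults by
#'   condition (1 for control, 1.1765 for sham/lhk).
#' @param schedule A [perturbation_schedule()]; defaults to empty, or to
#'   the standard kindling train for `lhk`.
#' @param initial_state Named molar state (default [hpa_initial_state()]).
#' @param t_start,t_end Span in minutes since 00:00 day 1 (default 5 days).
#' @param tolerances Preset name for [solver_tolerances()] or a
#'   `list(atol=, rtol=)` (default "strict").
#' @param k Rate constants.
#' @param forcing [forcing_params()].
#' @param output_dt Output grid spacing in minutes (<= 1 recommended for
#'   oscillation analytics).
#' @return List of class `scenario_config`.
#' @export
scenario_config <- function(condition = c("control", "sham", "lhk",
                                          "custom"),
                            k2_multiplier = NULL, schedule = NULL,
                            initial_state = hpa_initial_state(),
                            t_start = 0, t_end = 7200,
                            tolerances = "strict",
                            k = hpa_rate_constants(),
                            forcing = forcing_params(),
                            output_dt = 1) {
  condition <- match.arg(condition)
  if (is.null(k2_multiplier))
    k2_multiplier <- switch(condition, control = 1,
                            sham = 1.1765, lhk = 1.1765, custom = 1)
  if (is.null(schedule))
    schedule <- if (condition == "lhk")
      kindling_schedule(clock_to_minutes("21:12", day = 2))
    else perturbation_schedule()
  if (is.character(tolerances)) tolerances <- solver_tolerances(tolerances)
  stopifnot(t_end > t_start, k2_multiplier > 0,
            tolerances$atol > 0, tolerances$rtol > 0, output_dt > 0)
  if (nrow(schedule) &&
      (min(schedule$time) < t_start || max(schedule$time) >= t_end))
    stop("schedule events must lie within [t_start, t_end)")
  structure(list(condition = condition, k2_multiplier = k2_multiplier,
                 schedule = schedule,
                 initial_state = initial_state[hpa_species()],
                 t_start = t_start, t_end = t_end,
                 atol = tolerances$atol, rtol = tolerances$rtol,
                 k = k, forcing = forcing, output_dt = output_dt),
            class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf(
    "HPA scenario '%s': t = [%g, %g] min (%.1f days), k2 x %.4f, %d pulse(s)\n",
    x$condition, x$t_start, x$t_end, (x$t_end - x$t_start) / 1440,
    x$k2_multiplier, nrow(x$schedule)))
  cat(sprintf("  solver: bdf, atol %.1e, rtol %.1e, output every %g min\n",
              x$atol, x$rtol, x$output_dt))
  invisible(x)
}
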