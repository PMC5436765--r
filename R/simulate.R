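# Stiff integration of scenarios, with stop-and-restart pulse handling.

# RHS in the signature deSolve expects. Mirrors mass_action_rhs() but skips
# input validation: stiff solvers probe the RHS at trial states that may be
# transiently (and harmlessly) negative within tolerance. Agreement with
# mass_action_rhs() is asserted by the test suite.
.hpa_ode_rhs <- function(t, y, p) {
  k <- p$k
  D <- circadian_drive(t, p$forcing) * p$k2_multiplier
  CHOL <- y[1]; CRH <- y[2]; ALDO <- y[3]; ACTH <- y[4]; PNN <- y[5]
  PGS <- y[6]; DCTS <- y[7]; CTS <- y[8]; HPNN <- y[9]; HPGS <- y[10]
  CORT <- y[11]
  list(c(
    k[1] - k[5] * ACTH * CHOL - k[18] * CHOL,
    k[2] * D - k[16] * CRH * CTS - k[19] * CRH,
    k[3] + k[9] * CTS - k[15] * ALDO * CTS^2 - k[22] * ALDO,
    k[4] * CRH - k[5] * ACTH * CHOL - k[17] * ACTH * CTS - k[20] * ACTH,
    k[5] * ACTH * CHOL - (k[6] + k[11] + k[24]) * PNN,
    k[6] * PNN - (k[7] + k[10] + k[25]) * PGS,
    k[7] * PGS - k[8] * DCTS - k[14] * DCTS * CTS^2,
    k[8] * DCTS - k[9] * CTS + k[14] * DCTS * CTS^2 -
      k[15] * ALDO * CTS^2 - k[16] * CRH * CTS - k[17] * ACTH * CTS -
      k[21] * CTS,
    k[11] * PNN - k[12] * HPNN,
    k[10] * PGS + k[12] * HPNN - k[13] * HPGS,
    k[13] * HPGS - k[23] * CORT))
}

#' Integrate a scenario
#'
#' Runs a stiff backward-differentiation (Gear) solver piecewise between
#' pulse events. At each event the
#' integration stops, [apply_pulse()] raises the target species by the
#' event's increment, and integration restarts from the perturbed state --
#' the stop-and-restart protocol. The effective CRH production rate is
#' `k2 * k2_multiplier * D(t)` throughout.
#'
#' The returned trajectory reports states on the requested output grid plus
#' every event time; the row stored at an event time is the post-pulse
#' state, and the exact pre/post pulse states are kept separately for
#' bookkeeping. Magnitudes below 1e-30 M are floored to zero.
#'
#' @param scenario A [scenario_config()].
#' @return Object of class `hpa_trajectory`: list with `times` (strictly
#'   increasing minutes), `states` (rows = times, columns = species, M),
#'   `scenario`, `pulse_times`, `pulse_pre`, `pulse_post`.
#' @export
simulate_scenario <- function(scenario) {
  stopifnot(inherits(scenario, "scenario_config"))
  sc <- scenario
  k <- unname(sc$k)
  parms <- list(k = k, k2_multiplier = sc$k2_multiplier,
                forcing = sc$forcing)
  grid <- seq(sc$t_start, sc$t_end, by = sc$output_dt)
  if (grid[length(grid)] < sc$t_end) grid <- c(grid, sc$t_end)

  ev <- sc$schedule
  ev_at_start <- nrow(ev) > 0 & ev$time == sc$t_start
  y <- unname(sc$initial_state)
  pre_list <- list(); post_list <- list()
  if (any(ev_at_start)) {
    for (i in which(ev_at_start)) {
      pre_list[[length(pre_list) + 1L]] <- y
      st <- y; names(st) <- hpa_species()
      st <- apply_pulse(st, ev$species[i], ev$increment[i])
      y <- unname(st)
      post_list[[length(post_list) + 1L]] <- y
    }
    ev <- ev[!ev_at_start, , drop = FALSE]
  }
  bounds <- c(sc$t_start, ev$time, sc$t_end)
  times_all <- sort(unique(c(grid, ev$time)))

  n_seg <- length(bounds) - 1L
  out_times <- numeric(0)
  rows <- vector("list", n_seg)
  for (s in seq_len(n_seg)) {
    a <- bounds[s]; b <- bounds[s + 1L]
    i0 <- findInterval(a, times_all); i1 <- findInterval(b, times_all)
    inner <- times_all[seq.int(i0, i1)]
    seg_times <- unique(c(a, inner[inner > a & inner < b], b))
    if (s > 1L) {
      # segment opens at an event: record pre state, pulse, restart
      pre_list[[length(pre_list) + 1L]] <- y
      st <- y; names(st) <- hpa_species()
      st <- apply_pulse(st, ev$species[s - 1L], ev$increment[s - 1L])
      y <- unname(st)
      post_list[[length(post_list) + 1L]] <- y
    }
    res <- deSolve::ode(y, seg_times, .hpa_ode_rhs, parms,
                        method = "bdf", rtol = sc$rtol, atol = sc$atol,
                        maxsteps = 500000)
    if (attr(res, "istate")[1L] < 0)
      stop(sprintf("solver failure in [%g, %g]; last good time %g",
                   a, b, res[nrow(res), 1L]))
    m <- unclass(res)
    if (any(!is.finite(m))) stop("non-finite state in segment [", a, ", ",
                                 b, "]")
    y <- unname(m[nrow(m), -1L])
    if (s > 1L) {
      # keep the post-pulse row at the event time, drop the pre-pulse row
      rows[[s - 1L]] <- rows[[s - 1L]][-nrow(rows[[s - 1L]]), , drop = FALSE]
    }
    rows[[s]] <- m
  }
  m <- do.call(rbind, rows)
  times <- m[, 1L]
  states <- m[, -1L, drop = FALSE]
  states[abs(states) < 1e-30] <- 0
  colnames(states) <- hpa_species()
  name_mat <- function(lst) {
    if (!length(lst)) return(NULL)
    m <- do.call(rbind, lst)
    dimnames(m) <- list(NULL, hpa_species())
    m
  }
  structure(list(times = times, states = states, scenario = sc,
                 pulse_times = sc$schedule$time,
                 pulse_pre = name_mat(pre_list),
                 pulse_post = name_mat(post_list)),
            class = "hpa_trajectory")
}

#' @export
print.hpa_trajectory <- function(x, ...) {
  cat(sprintf(
    "HPA trajectory ('%s'): %d time points over [%g, %g] min, %d pulse(s)\n",
    x$scenario$condition %||% "?", length(x$times), min(x$times),
    max(x$times), length(x$pulse_times)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Extract one species' time series from a trajectory
#'
#' @param traj An `hpa_trajectory`.
#' @param species One of [hpa_species()].
#' @param window Optional `c(t_min, t_max)` in minutes (inclusive).
#' @return data.frame with `time` (min) and `value` (M).
#' @export
trajectory_series <- function(traj, species = "CTS", window = NULL) {
  stopifnot(inherits(traj, "hpa_trajectory"))
  if (!species %in% colnames(traj$states))
    stop("unknown species: ", species)
  keep <- rep(TRUE, length(traj$times))
  if (!is.null(window))
    keep <- traj$times >= window[1] & traj$times <= window[2]
  data.frame(time = traj$times[keep], value = traj$states[keep, species])
}

#' Write / read a trajectory as CSV
#'
#' Columns `time_min`, `clock` (HH:MM), then one column per species in
#' molar units, written at full double precision so values round-trip
#' losslessly.
#'
#' @param traj An `hpa_trajectory`.
#' @param path File path.
#' @return `write_trajectory_csv` returns `path` invisibly;
#'   `read_trajectory_csv` returns an `hpa_trajectory` (without scenario or
#'   pulse bookkeeping, which live in the run configuration).
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "hpa_trajectory"))
  df <- data.frame(time_min = sprintf("%.17g", traj$times),
                   clock = minutes_to_clock(traj$times),
                   stringsAsFactors = FALSE)
  for (sp in colnames(traj$states))
    df[[sp]] <- sprintf("%.17g", traj$states[, sp])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  sp <- setdiff(names(df), c("time_min", "clock"))
  states <- vapply(sp, function(s) as.numeric(df[[s]]),
                   numeric(nrow(df)))
  colnames(states) <- sp
  structure(list(times = as.numeric(df$time_min), states = states,
                 scenario = NULL, pulse_times = numeric(0),
                 pulse_pre = NULL, pulse_post = NULL),
            class = "hpa_trajectory")
}
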