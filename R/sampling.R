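# Synthetic blood-sampling schedules and ELISA measurement noise.

#' Blood-sampling schedules
#'
#' The two 31-sample, 24-h schedules used around a kindling window, both
#' drawing 50 uL per sample (1.55 mL total):
#' \itemize{
#'   \item Variant A: samples 1--23 hourly (the last one 60 min before
#'     kindling start), samples 24--29 every 10 min during the 50-min
#'     kindling window, samples 30--31 every 30 min after it.
#'   \item Variant B: sample 1 at 50 min before kindling, samples 2--7
#'     every 10 min during kindling, samples 8--31 hourly afterwards.
#' }
#' The clock anchoring of the hourly run-in of variant A is a convention
#' (set by `kindle_start`); the in-kindling samples are anchored to the
#' kindling window itself.
#'
#' @param variant "A" or "B".
#' @param kindle_start Kindling start, minutes since 00:00 day 1 (default
#'   21:12 on day 2).
#' @param kindle_duration_min Kindling window length (min).
#' @param per_sample_volume_uL Volume drawn per sample (uL).
#' @return data.frame of class `sampling_schedule` with columns `sample`
#'   and `time_min`; attributes `variant` and `per_sample_volume_uL`.
#' @export
make_schedule <- function(variant = c("A", "B"),
                          kindle_start = clock_to_minutes("21:12", day = 2),
                          kindle_duration_min = 50,
                          per_sample_volume_uL = 50) {
  variant <- match.arg(variant)
  ks <- kindle_start; ke <- kindle_start + kindle_duration_min
  times <- if (variant == "A") {
    c(ks - 60 * (23:1),            # 1-23 hourly, ending 1 h before kindling
      seq(ks, ke, by = 10),        # 24-29 every 10 min during kindling
      ke + c(30, 60))              # 30-31 every 30 min after
  } else {
    c(ks - 50,                     # 1: 50 min before kindling
      seq(ks, ke, by = 10),        # 2-7 every 10 min during kindling
      ke + 60 * (1:24))            # 8-31 hourly afterwards
  }
  stopifnot(length(times) == 31, all(diff(times) > 0))
  out <- data.frame(sample = seq_along(times), time_min = times)
  attr(out, "variant") <- variant
  attr(out, "per_sample_volume_uL") <- per_sample_volume_uL
  class(out) <- c("sampling_schedule", "data.frame")
  out
}

#' Total drawn blood volume of a schedule
#'
#' @param schedule A [make_schedule()] object.
#' @return Volume in mL (sample count x per-sample volume).
#' @export
total_drawn_volume_ml <- function(schedule) {
  stopifnot(inherits(schedule, "sampling_schedule"))
  nrow(schedule) * attr(schedule, "per_sample_volume_uL") / 1000
}

#' ELISA measurement-noise model
#'
#' Multiplicative log-normal noise with median 1 and coefficient of
#' variation `cv` (the published inter-assay CV is 4.1%), plus independent
#' sample loss with probability `missingness_prob`. The log-normal choice
#' keeps synthetic assay values nonnegative and is median-unbiased.
#'
#' @param cv Coefficient of variation (fraction, default 0.041).
#' @param missingness_prob Probability a drawn sample is lost, in [0, 1).
#' @param seed Integer seed making draws reproducible.
#' @return List of class `noise_model`; `sdlog` is the log-scale standard
#'   deviation implied by `cv`.
#' @export
noise_model <- function(cv = 0.041, missingness_prob = 0, seed = NULL) {
  stopifnot(cv >= 0, missingness_prob >= 0, missingness_prob < 1)
  structure(list(cv = cv, sdlog = sqrt(log1p(cv^2)),
                 missingness_prob = missingness_prob, seed = seed),
            class = "noise_model")
}

#' Draw one synthetic animal's corticosterone measurements
#'
#' Evaluates the trajectory's corticosterone at the schedule's times,
#' converts to ng/mL, applies multiplicative log-normal assay noise and
#' random sample loss. Lost samples keep their schedule row with `NA`
#' value and `missing = TRUE`.
#'
#' @param traj An `hpa_trajectory` spanning all schedule times.
#' @param schedule A [make_schedule()] object (or data.frame with
#'   `time_min`).
#' @param noise A [noise_model()].
#' @param molar_mass Molar mass used for the unit conversion (g/mol).
#' @param animal_id,group Labels carried as attributes.
#' @return data.frame of class `sampled_series` with columns `sample`,
#'   `time_min`, `clock`, `value_ng_ml`, `missing`.
#' @export
sample_trajectory <- function(traj, schedule, noise = noise_model(),
                              molar_mass = 346.46,
                              animal_id = "animal_1", group = "control") {
  stopifnot(inherits(traj, "hpa_trajectory"),
            inherits(noise, "noise_model"))
  tms <- schedule$time_min
  bad <- tms < min(traj$times) | tms > max(traj$times)
  if (any(bad))
    stop("schedule time(s) outside trajectory span: ",
         paste(tms[bad], collapse = ", "))
  cts <- stats::approx(traj$times, traj$states[, "CTS"], xout = tms,
                       ties = "ordered")$y
  true_ng <- molar_to_ng_per_ml(cts, molar_mass)
  if (!is.null(noise$seed)) set.seed(noise$seed)
  fac <- if (noise$cv > 0)
    stats::rlnorm(length(tms), meanlog = 0, sdlog = noise$sdlog)
  else rep(1, length(tms))
  lost <- if (noise$missingness_prob > 0)
    stats::runif(length(tms)) < noise$missingness_prob
  else rep(FALSE, length(tms))
  value <- true_ng * fac
  value[lost] <- NA_real_
  out <- data.frame(sample = seq_along(tms), time_min = tms,
                    clock = minutes_to_clock(tms),
                    value_ng_ml = value, missing = lost)
  attr(out, "animal_id") <- animal_id
  attr(out, "group") <- group
  attr(out, "seed") <- noise$seed
  attr(out, "variant") <- attr(schedule, "variant")
  class(out) <- c("sampled_series", "data.frame")
  out
}

#' Generate a synthetic cohort
#'
#' Draws `n_per_group` animals per condition from the supplied group
#' trajectories, with per-animal seeds derived deterministically from the
#' master seed, so a cohort regenerates bit-identically. Inter-animal
#' variability comes from the measurement-noise draws; optionally a
#' per-animal jitter on the stress multiplier can be emulated upstream by
#' passing per-animal trajectories in `trajectories` (a list of lists).
#'
#' @param trajectories Named list of `hpa_trajectory` objects, one per
#'   group (e.g. `list(control = ..., sham = ..., kindled = ...)`), or a
#'   list of per-animal trajectory lists of the same shape.
#' @param n_per_group Named integer vector of animals per group.
#' @param schedule A [make_schedule()] object used for every animal.
#' @param cv,missingness_prob Noise parameters, see [noise_model()].
#' @param seed Master seed.
#' @param molar_mass Molar mass for unit conversion (g/mol).
#' @return List of class `hpa_cohort` of [sample_trajectory()] results;
#'   attribute `seed` records the master seed.
#' @export
make_cohort <- function(trajectories,
                        n_per_group = c(control = 3, sham = 4,
                                        kindled = 4),
                        schedule = make_schedule("B"),
                        cv = 0.041, missingness_prob = 0, seed = 1,
                        molar_mass = 346.46) {
  stopifnot(all(names(n_per_group) %in% names(trajectories)),
            all(n_per_group >= 1))
  out <- list()
  idx <- 0L
  for (g in names(n_per_group)) {
    for (i in seq_len(n_per_group[[g]])) {
      idx <- idx + 1L
      tr <- trajectories[[g]]
      if (!inherits(tr, "hpa_trajectory")) tr <- tr[[i]]
      nm <- noise_model(cv, missingness_prob, seed = seed + idx)
      out[[idx]] <- sample_trajectory(tr, schedule, nm, molar_mass,
                                      animal_id = paste0(g, "_", i),
                                      group = g)
    }
  }
  attr(out, "seed") <- seed
  class(out) <- "hpa_cohort"
  out
}

#' Flatten a cohort (or one series) to a tidy table
#'
#' @param x An `hpa_cohort` or `sampled_series`.
#' @param ... Unused.
#' @return data.frame with `animal_id`, `group`, `seed`, `sample`,
#'   `time_min`, `clock`, `value_ng_ml`, `missing`.
#' @export
cohort_table <- function(x, ...) {
  series <- if (inherits(x, "hpa_cohort")) x else list(x)
  do.call(rbind, lapply(series, function(s) {
    data.frame(animal_id = attr(s, "animal_id") %||% NA_character_,
               group = attr(s, "group") %||% NA_character_,
               seed = attr(s, "seed") %||% NA_integer_,
               s, stringsAsFactors = FALSE)
  }))
}

#' Write / read a cohort as tidy CSV
#'
#' Values are written at full double precision; reading reconstructs the
#' list of `sampled_series` with their animal, group and seed attributes.
#'
#' @param cohort An `hpa_cohort`.
#' @param path File path.
#' @return `write_cohort_csv` returns `path` invisibly; `read_cohort_csv`
#'   returns an `hpa_cohort`.
#' @export
write_cohort_csv <- function(cohort, path) {
  df <- cohort_table(cohort)
  df$time_min <- sprintf("%.17g", df$time_min)
  df$value_ng_ml <- ifelse(is.na(df$value_ng_ml), "",
                           sprintf("%.17g", df$value_ng_ml))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(time_min = "character",
                                       value_ng_ml = "character"))
  out <- lapply(split(df, factor(df$animal_id,
                                 levels = unique(df$animal_id))),
                function(a) {
    s <- data.frame(sample = a$sample,
                    time_min = as.numeric(a$time_min),
                    clock = a$clock,
                    value_ng_ml = suppressWarnings(
                      as.numeric(ifelse(a$value_ng_ml == "", NA,
                                        a$value_ng_ml))),
                    missing = a$missing)
    attr(s, "animal_id") <- a$animal_id[1]
    attr(s, "group") <- a$group[1]
    attr(s, "seed") <- a$seed[1]
    class(s) <- c("sampled_series", "data.frame")
    s
  })
  names(out) <- NULL
  class(out) <- "hpa_cohort"
  out
}
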