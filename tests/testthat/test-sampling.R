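# A flat trajectory is enough to exercise the measurement model.
flat_trajectory <- function(value_M = 2e-7, t_end = 4320) {
  times <- seq(0, t_end)
  states <- matrix(value_M, nrow = length(times), ncol = 11,
                   dimnames = list(NULL, hpa_species()))
  structure(list(times = times, states = states, scenario = NULL,
                 pulse_times = numeric(0)),
            class = "hpa_trajectory")
}

test_that("both printed schedules have 31 samples drawing 1.55 mL", {
  for (v in c("A", "B")) {
    sch <- make_schedule(v)
    expect_equal(nrow(sch), 31)
    expect_true(all(diff(sch$time_min) > 0))
    expect_equal(total_drawn_volume_ml(sch), 1.55)
  }
})

test_that("schedule variants are anchored to the kindling window", {
  ks <- clock_to_minutes("21:12", day = 2)
  a <- make_schedule("A", kindle_start = ks)
  # samples 1-23 hourly, 24-29 every 10 min during kindling, 30-31 after
  expect_equal(diff(a$time_min[1:23]), rep(60, 22))
  expect_equal(diff(a$time_min[24:29]), rep(10, 5))
  expect_true(all(a$time_min[24:29] >= ks & a$time_min[24:29] <= ks + 50))
  expect_equal(diff(a$time_min[30:31]), 30)
  expect_true(all(a$time_min[30:31] > ks + 50))
  b <- make_schedule("B", kindle_start = ks)
  expect_equal(b$time_min[1], ks - 50)
  inside <- b$time_min >= ks & b$time_min <= ks + 50
  expect_equal(sum(inside), 6)
  expect_equal(diff(b$time_min[inside]), rep(10, 5))
  expect_equal(diff(b$time_min[8:31]), rep(60, 23))
})

test_that("noiseless sampling reproduces the converted trajectory exactly", {
  tr <- flat_trajectory(2e-7)
  sch <- make_schedule("B")
  s <- sample_trajectory(tr, sch, noise_model(cv = 0))
  expect_equal(nrow(s), 31)
  expect_false(any(s$missing))
  expect_equal(s$value_ng_ml, rep(molar_to_ng_per_ml(2e-7), 31),
               tolerance = 1e-15)
})

test_that("the log-normal noise reproduces the assay CV and is median-unbiased", {
  tr <- flat_trajectory(2e-7)
  sch <- data.frame(time_min = seq_len(10000) / 10)
  s <- sample_trajectory(tr, sch, noise_model(cv = 0.041, seed = 99))
  emp_cv <- stats::sd(s$value_ng_ml) / mean(s$value_ng_ml)
  expect_equal(emp_cv, 0.041, tolerance = 0.15 / 4.1)
  expect_equal(stats::median(s$value_ng_ml), molar_to_ng_per_ml(2e-7),
               tolerance = 2e-3)
})

test_that("sampling is reproducible by seed and missingness keeps schedule rows", {
  tr <- flat_trajectory()
  sch <- make_schedule("A")
  s1 <- sample_trajectory(tr, sch, noise_model(seed = 7))
  s2 <- sample_trajectory(tr, sch, noise_model(seed = 7))
  s3 <- sample_trajectory(tr, sch, noise_model(seed = 8))
  expect_identical(s1$value_ng_ml, s2$value_ng_ml)
  expect_false(identical(s1$value_ng_ml, s3$value_ng_ml))
  sm <- sample_trajectory(tr, sch,
                          noise_model(missingness_prob = 0.5, seed = 1))
  expect_equal(nrow(sm), 31)
  expect_true(any(sm$missing))
  expect_true(all(is.na(sm$value_ng_ml[sm$missing])))
  expect_true(all(!is.na(sm$value_ng_ml[!sm$missing])))
  # a schedule outside the trajectory span names the offending time
  bad <- data.frame(time_min = c(10, 99999))
  expect_error(sample_trajectory(tr, bad, noise_model()), "99999")
})

test_that("cohorts are labelled, reproducible, and round-trip through CSV", {
  trajs <- list(control = flat_trajectory(1.5e-7),
                sham = flat_trajectory(2.5e-7),
                kindled = flat_trajectory(4e-7))
  ch <- make_cohort(trajs, n_per_group = c(control = 3, sham = 4,
                                           kindled = 4),
                    seed = 5, missingness_prob = 0.1)
  expect_length(ch, 11)
  groups <- vapply(ch, function(s) attr(s, "group"), "")
  expect_equal(unname(table(groups)[c("control", "sham", "kindled")]),
               c(3L, 4L, 4L), ignore_attr = TRUE)
  ch2 <- make_cohort(trajs, n_per_group = c(control = 3, sham = 4,
                                            kindled = 4),
                     seed = 5, missingness_prob = 0.1)
  expect_identical(cohort_table(ch), cohort_table(ch2))
  # in the noiseless limit the kindled group mean exceeds control
  chn <- make_cohort(trajs, n_per_group = c(control = 2, kindled = 2),
                     cv = 0, seed = 1)
  tab <- cohort_table(chn)
  expect_gt(mean(tab$value_ng_ml[tab$group == "kindled"]),
            mean(tab$value_ng_ml[tab$group == "control"]))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(ch, path)
  back <- read_cohort_csv(path)
  expect_equal(length(back), length(ch))
  expect_identical(cohort_table(back)$value_ng_ml,
                   cohort_table(ch)$value_ng_ml)
  expect_identical(vapply(back, function(s) attr(s, "group"), ""),
                   groups)
})
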