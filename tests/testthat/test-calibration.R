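# Short kindling scenarios keep each candidate simulation cheap; the
# relaxed tolerances are adequate here because residuals live on the
# corticosterone (ng/mL) scale.
short_lhk <- function(intensity)
  lhk_scenario(intensity, kindle_start = 600, t_end = 2200,
               tolerances = "relaxed")

short_sham <- function(m)
  scenario_config("custom", k2_multiplier = m, t_end = 2880,
                  tolerances = "relaxed")

test_that("pulse intensity is identified exactly from noiseless data", {
  sch <- make_schedule("B", kindle_start = 600)
  truth <- simulate_scenario(short_lhk(5e-8))
  series <- lapply(1:2, function(i)
    sample_trajectory(truth, sch, noise_model(cv = 0),
                      animal_id = paste0("kindled_", i),
                      group = "kindled"))
  cand <- c(1e-8, 2e-8, 5e-8, 1e-7)
  fit <- fit_pulse_intensity(series, cand,
                             scenario_for_intensity = short_lhk)
  expect_identical(fit$estimate, 5e-8)
  expect_identical(fit$objective, 0)
  # objective grows monotonically along the grid away from the truth
  obj <- fit$trace$objective
  expect_true(obj[1] > obj[2])
  expect_true(obj[2] > obj[3])
  expect_true(obj[4] > obj[3])
  expect_false(any(fit$trace$failed))
})

test_that("pre-simulated candidate trajectories give the same fit", {
  sch <- make_schedule("B", kindle_start = 600)
  truth <- simulate_scenario(short_lhk(5e-8))
  s <- sample_trajectory(truth, sch, noise_model(cv = 0.041, seed = 3),
                         group = "kindled")
  cand <- c(2e-8, 5e-8, 1e-7)
  sims <- simulate_candidates(cand, short_lhk)
  f1 <- fit_pulse_intensity(list(s), cand,
                            scenario_for_intensity = short_lhk)
  f2 <- fit_pulse_intensity(list(s), cand, candidate_trajectories = sims)
  expect_identical(f1$estimate, f2$estimate)
  expect_identical(f1$trace$objective, f2$trace$objective)
})

test_that("the sham stress multiplier is recovered from noiseless data", {
  sch <- data.frame(time_min = 1440 + 60 * (0:23))
  sham <- simulate_scenario(short_sham(1.1765))
  s <- sample_trajectory(sham, sch, noise_model(cv = 0), group = "sham")
  fit <- fit_stress_multiplier(list(s), bounds = c(1, 1.4),
                               scenario_for_multiplier = short_sham)
  expect_lt(abs(fit$estimate - 1.1765), 0.01)
  # at the generating value itself the model matches its own data exactly
  expect_identical(hpaxis:::sum_sq_residuals(list(s), sham), 0)
  # the reported optimum is no worse than any evaluated grid candidate
  expect_lte(fit$objective, min(fit$trace$objective))
  # control data pulls the estimate down to (or below) the sham value
  ctrl <- simulate_scenario(short_sham(1))
  sc <- sample_trajectory(ctrl, sch, noise_model(cv = 0),
                          group = "control")
  fit0 <- fit_stress_multiplier(list(sc), bounds = c(1, 1.4),
                                scenario_for_multiplier = short_sham)
  expect_lte(fit0$estimate, fit$estimate)
  expect_lt(abs(fit0$estimate - 1), 0.01)
})

test_that("one-way ANOVA behaves as the classical statistic", {
  set.seed(21)
  df <- data.frame(group = rep(c("a", "b", "c"), each = 18),
                   value = stats::rnorm(54, 100, 5))
  r0 <- group_comparison(df)
  expect_identical(r0$df1, 2)
  expect_identical(r0$df2, 51)
  # adding a constant to one group strictly increases F
  df2 <- df
  df2$value[df2$group == "a"] <- df2$value[df2$group == "a"] + 10
  expect_gt(group_comparison(df2)$F, r0$F)
  # scaling every value leaves F unchanged
  df3 <- df
  df3$value <- df3$value * 7.3
  expect_equal(group_comparison(df3)$F, r0$F, tolerance = 1e-10)
  expect_error(group_comparison(df[df$group == "a", ]), ">= 2 groups")
})
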