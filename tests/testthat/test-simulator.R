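test_that("apply_pulse is exact, additive, and leaves other species alone", {
  st <- hpa_initial_state()
  st[["CRH"]] <- 2e-13
  out <- apply_pulse(st, "CRH", 5e-8)
  expect_identical(out[["CRH"]], 2e-13 + 5e-8)
  expect_equal(out[["CRH"]], 5.00002e-8, tolerance = 1e-15)
  expect_identical(out[setdiff(names(out), "CRH")],
                   st[setdiff(names(st), "CRH")])
  expect_identical(apply_pulse(st, "CTS", 0), st)
  # two successive pulses equal one combined pulse
  expect_identical(apply_pulse(apply_pulse(st, "CRH", 1e-9), "CRH", 3e-9),
                   apply_pulse(st, "CRH", 4e-9))
  expect_error(apply_pulse(st, "XYZ", 1e-9), "unknown species")
  expect_error(apply_pulse(st, "CRH", -1e-9), ">= 0")
})

test_that("the kindling schedule spans the 50-min window with 75 pulses", {
  start <- clock_to_minutes("21:12", day = 2)
  expect_identical(start, 2712)
  sch <- kindling_schedule(start)
  expect_equal(nrow(sch), 75)
  expect_true(all(sch$time >= start))
  expect_true(all(sch$time < start + 50))
  expect_equal(diff(sch$time), rep(40 / 60, 74), tolerance = 1e-12)
  expect_equal(max(sch$time), start + 74 * 40 / 60, tolerance = 1e-12)
  expect_true(all(sch$species == "CRH"))
  expect_true(all(sch$increment == 5e-8))
  expect_equal(nrow(kindling_schedule(start, duration_min = 0)), 0)
})

test_that("perturbation schedules validate their invariants", {
  expect_error(perturbation_schedule(c(10, 10), "CRH", 1e-9),
               "strictly increasing")
  expect_error(perturbation_schedule(c(10, 20), "CRH", -1e-9), ">= 0")
  expect_error(perturbation_schedule(10, "NOPE", 1e-9), "unknown species")
})

test_that("scenario presets carry the published settings", {
  ctrl <- scenario_config("control")
  expect_identical(ctrl$k2_multiplier, 1)
  expect_identical(ctrl$atol, 3e-20)
  expect_identical(ctrl$rtol, 1e-14)
  expect_equal(nrow(ctrl$schedule), 0)
  expect_identical(unname(ctrl$initial_state["CTS"]), 4.00e-8)
  sham <- scenario_config("sham")
  expect_identical(sham$k2_multiplier, 1.1765)
  lhk <- scenario_config("lhk")
  expect_identical(lhk$k2_multiplier, 1.1765)
  expect_equal(nrow(lhk$schedule), 75)
  expect_error(scenario_config("control", t_start = 10, t_end = 5),
               "t_end > t_start")
})

test_that("pulse bookkeeping is exact through a kindled integration", {
  sch <- kindling_schedule(600, intensity = 5e-8)
  sc <- scenario_config("custom", k2_multiplier = 1.1765,
                        schedule = sch, t_end = 780,
                        tolerances = "standard")
  tr <- simulate_scenario(sc)
  expect_equal(length(tr$pulse_times), 75)
  expect_equal(nrow(tr$pulse_pre), 75)
  delta <- tr$pulse_post[, 2] - tr$pulse_pre[, 2]
  expect_lt(max(abs(delta - 5e-8) / 5e-8), 1e-15)
  # non-pulsed species are bit-identical across each restart
  expect_identical(tr$pulse_post[, -2], tr$pulse_pre[, -2])
  # trajectory times are strictly increasing and cover the span
  expect_true(all(diff(tr$times) > 0))
  expect_identical(range(tr$times), c(0, 780))
  # the trajectory rows at pulse times hold the post-pulse state
  i <- match(tr$pulse_times[1], tr$times)
  expect_identical(unname(tr$states[i, "CRH"]),
                   unname(tr$pulse_post[1, 2]))
})

test_that("integration is deterministic and keeps states positive", {
  sc <- scenario_config("control", t_end = 2880,
                        tolerances = "standard")
  a <- simulate_scenario(sc)
  b <- simulate_scenario(sc)
  expect_identical(a$states, b$states)
  expect_gt(min(a$states), 0)
})

test_that("trajectories round-trip through CSV at full precision", {
  sc <- scenario_config("control", t_end = 60, output_dt = 7,
                        tolerances = "standard")
  tr <- simulate_scenario(sc)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory_csv(tr, path)
  back <- read_trajectory_csv(path)
  expect_identical(back$times, tr$times)
  expect_identical(back$states, tr$states)
})

test_that("clock helpers convert both ways", {
  expect_identical(clock_to_minutes("00:00"), 0)
  expect_identical(clock_to_minutes("14:00"), 840)
  expect_identical(clock_to_minutes("21:12", day = 2), 2712)
  expect_identical(minutes_to_clock(2712), "21:12")
  expect_identical(minutes_to_clock(c(0, 1439, 1440)),
                   c("00:00", "23:59", "00:00"))
  expect_error(clock_to_minutes("25:00"), "invalid")
})
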