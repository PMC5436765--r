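make_sinusoid <- function(period = 80, days = 2, amp = 0.5, base = 10,
                          circ_amp = 2, dt = 1) {
  t <- seq(0, days * 1440, by = dt)
  data.frame(time = t, value = base + circ_amp * sin(2 * pi * t / 1440) +
               amp * sin(2 * pi * t / period))
}

test_that("a known ultradian period rides through detrending and peak picking", {
  ser <- make_sinusoid(period = 80)
  m <- detect_ultradian(ser)
  expect_true(m$oscillations_present)
  expect_equal(m$ultradian_period_min, 80, tolerance = 1 / 80)
  expect_equal(m$ultradian_frequency_per_day, 1440 / 80, tolerance = 0.06)
  # amplitude is peak minus following trough on the raw series
  expect_equal(m$ultradian_amplitude_M, 2 * 0.5, tolerance = 0.25)
})

test_that("peak detection is invariant to uniform scaling", {
  ser <- make_sinusoid(period = 60)
  m1 <- detect_ultradian(ser)
  ser$value <- ser$value * 1e6
  m2 <- detect_ultradian(ser)
  expect_identical(m1$n_peaks, m2$n_peaks)
  expect_identical(m1$ultradian_period_min, m2$ultradian_period_min)
  expect_equal(m2$ultradian_amplitude_M,
               1e6 * m1$ultradian_amplitude_M, tolerance = 1e-9)
})

test_that("largest-amplitude bounds bracket every detected extremum pair", {
  # amplitude-modulated pulsatility: the largest swing carries both the
  # highest peak and the lowest trough
  t <- seq(0, 2880)
  ser <- data.frame(time = t,
                    value = 10 + (2 + sin(2 * pi * t / 1440)) *
                      sin(2 * pi * t / 90))
  m <- detect_ultradian(ser)
  b <- m$largest_amplitude_bounds_M
  rs <- hpaxis:::resample_series(ser$time, ser$value)
  expect_gte(b[["peak"]],
             max(rs$value[match(m$peak_times, rs$time)]) - 1e-9)
  expect_lte(b[["trough"]],
             min(rs$value[match(m$trough_times, rs$time)]) + 1e-9)
})

test_that("sparse oscillations are flagged absent, not zero", {
  t <- seq(0, 2880)
  m <- detect_ultradian(data.frame(time = t, value = rep(5, length(t))))
  expect_false(m$oscillations_present)
  expect_true(is.na(m$ultradian_period_min))
  expect_true(is.na(m$ultradian_amplitude_M))
})

test_that("the autocorrelation period estimator hits an exact 24 h rhythm", {
  t <- seq(0, 6 * 1440)
  ser <- data.frame(time = t, value = 3 + sin(2 * pi * t / 1440))
  expect_identical(circadian_period_estimate(ser), 24)
  short <- ser[ser$time <= 3 * 1440, ]
  expect_error(circadian_period_estimate(short), "4 full days")
})

test_that("molar / assay-unit conversion is exact and invertible", {
  expect_identical(molar_to_ng_per_ml(0), 0)
  expect_equal(molar_to_ng_per_ml(2.08e-7, 346.46), 72.06,
               tolerance = 1e-4)
  x <- c(1e-9, 4e-8, 2.08e-7)
  expect_lt(max(rel_err(ng_per_ml_to_molar(molar_to_ng_per_ml(x)), x)),
            1e-12)
  expect_error(molar_to_ng_per_ml(-1e-9), "nonnegative")
})

test_that("CRH stimulation-test concentrations come out at the published order", {
  rat <- stimulation_test_concentration(10, blood_ml_per_kg = 70)
  expect_identical(signif(rat, 1), 3e-8)
  human <- stimulation_test_concentration(1, blood_volume_l = 5.25,
                                          body_mass_kg = 70)
  expect_identical(signif(human, 1), 3e-9)
  expect_identical(stimulation_test_concentration(0,
                                                  blood_ml_per_kg = 70), 0)
  # inconsistent blood-volume specifications are rejected
  expect_error(stimulation_test_concentration(10, blood_volume_l = 5,
                                              blood_ml_per_kg = 70),
               "exactly one")
  expect_error(stimulation_test_concentration(10, blood_volume_l = 5),
               "body_mass_kg")
})
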