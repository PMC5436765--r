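test_that("the rat network has 11 species and 25 reactions with the printed constants", {
  net <- build_rat_network()
  expect_length(net$species, 11)
  expect_length(unique(net$species), 11)
  expect_length(net$reactions, 25)
  k <- hpa_rate_constants()
  expect_identical(k[["k1"]], 5.5200e-5)
  expect_identical(k[["k2"]], 2.2875e-8)
  expect_identical(k[["k14"]], 1.5120e12)
  expect_identical(k[["k25"]], 1.0000e-5)
  expect_true(all(k > 0))
  # every species appears in at least one reaction
  expect_true(all(rowSums(abs(net$stoichiometry)) > 0))
})

test_that("reaction structure matches the printed stoichiometric relations", {
  net <- build_rat_network()
  rx <- setNames(net$reactions, vapply(net$reactions, `[[`, "", "label"))
  # R14: DCTS + 2CTS -> 3CTS; net column +1 CTS, -1 DCTS
  expect_equal(rx$R14$reactants, c(DCTS = 1, CTS = 2))
  expect_equal(rx$R14$products, c(CTS = 3))
  col <- net$stoichiometry[, "R14"]
  expect_equal(col[["CTS"]], 1L)
  expect_equal(col[["DCTS"]], -1L)
  expect_true(all(col[setdiff(names(col), c("CTS", "DCTS"))] == 0L))
  # R15: ALDO + 2CTS -> CTS; net {ALDO: -1, CTS: -1}
  expect_equal(rx$R15$reactants, c(ALDO = 1, CTS = 2))
  expect_equal(net$stoichiometry[["ALDO", "R15"]], -1L)
  expect_equal(net$stoichiometry[["CTS", "R15"]], -1L)
  # R16 consumes one CRH and one CTS and produces nothing
  expect_equal(rx$R16$reactants, c(CRH = 1, CTS = 1))
  expect_length(rx$R16$products, 0)
  # feedback and elimination steps have empty product sets
  for (lab in c("R16", "R17", paste0("R", 18:25)))
    expect_length(rx[[lab]]$products, 0)
  # only R2 is circadian-forced
  forced <- vapply(net$reactions, `[[`, logical(1), "forced_by_circadian")
  expect_identical(which(forced), 2L)
  # orders in {0,...,3} with unit strings consistent
  ord <- vapply(net$reactions, `[[`, integer(1), "order")
  expect_true(all(ord %in% 0:3))
  units <- vapply(net$reactions, `[[`, "", "units")
  expect_identical(units[ord == 0], rep("M min-1", sum(ord == 0)))
  expect_identical(units[ord == 3], rep("M-2 min-1", sum(ord == 3)))
})

test_that("reaction_rate computes mass-action fluxes", {
  net <- build_rat_network()
  rx <- setNames(net$reactions, vapply(net$reactions, `[[`, "", "label"))
  st <- setNames(rep(0, 11), hpa_species())
  st[["DCTS"]] <- 4e-9; st[["CTS"]] <- 4e-8
  expect_equal(reaction_rate(rx$R14, st), 1.5120e12 * 4e-9 * (4e-8)^2,
               tolerance = 1e-14)
  expect_equal(reaction_rate(rx$R14, st), 9.6768e-12, tolerance = 1e-12)
  # zeroth-order fluxes ignore the state; R2 scales with the drive
  zero <- setNames(rep(0, 11), hpa_species())
  expect_identical(reaction_rate(rx$R1, zero), 5.5200e-5)
  expect_identical(reaction_rate(rx$R2, zero, circadian_factor = 0.5),
                   2.2875e-8 * 0.5)
  # a zero reactant kills the flux
  expect_identical(reaction_rate(rx$R16, st), 0)  # CRH = 0
  # negative concentrations are rejected
  st[["CTS"]] <- -1e-9
  expect_error(reaction_rate(rx$R14, st), "negative")
})

test_that("order-n fluxes scale exactly as alpha^n (units audit)", {
  net <- build_rat_network()
  set.seed(42)
  st <- random_state()
  for (rx in net$reactions) {
    f1 <- reaction_rate(rx, st)
    f2 <- reaction_rate(rx, 2 * st)
    expect_identical(f2, 2^rx$order * f1)
  }
})

test_that("a network round-trips through its CSV representation", {
  net <- build_rat_network()
  path <- withr::local_tempfile(fileext = ".csv")
  write_network_csv(net, path)
  back <- read_network_csv(path)
  expect_identical(back$stoichiometry, net$stoichiometry)
  expect_identical(
    vapply(back$reactions, `[[`, numeric(1), "rate_constant"),
    vapply(net$reactions, `[[`, numeric(1), "rate_constant"))
})
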