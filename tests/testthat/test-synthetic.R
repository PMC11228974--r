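test_that("voltage grid merges coarse and refined ramps", {
  g <- make_voltage_grid(20, 60, 1, 42, 44, 0.5)
  expect_length(g, 43)               # 41 coarse + 42.5 + 43.5
  expect_false(is.unsorted(g, strictly = TRUE))
  expect_true(all(c(42.5, 43.5) %in% g))
  expect_length(make_voltage_grid(30, 60, 1, 30, 30, 1), 31)
  expect_error(make_voltage_grid(20, 60, 1, 10, 15, 1), "within")
  expect_error(make_voltage_grid(60, 20, 1, 30, 40, 1), "start")
  expect_error(make_voltage_grid(20, 60, -1, 42, 44, 0.5), "steps")
})

test_that("unfolded and survival fractions follow the logistic closed forms", {
  expect_equal(unfolded_fraction(42, 42, 1.3), 0.5)
  expect_equal(unfolded_fraction(-1e6, 42, 1), 0)
  expect_equal(unfolded_fraction(1e6, 42, 1), 1)
  expect_equal(unfolded_fraction(44, 42, 1.0), 1 / (1 + exp(-2)))
  expect_error(unfolded_fraction(40, 42, -1), "slope")

  expect_equal(survival_fraction(42, 42, 1.5), 0.5)
  expect_equal(survival_fraction(10, 42, 1.5), 1, tolerance = 1e-9)
  expect_equal(survival_fraction(45, 42, 1.5), 1 - 1 / (1 + exp(-4.5)))
  # monotonicity
  v <- seq(30, 60, 0.5)
  expect_true(all(diff(unfolded_fraction(v, 42, 0.8)) > 0))
  expect_true(all(diff(survival_fraction(v, 42, 0.8)) < 0))
})

apo <- species_params("apo", 33.8, 37.3, 40.3, 0.8, mass = 43313, charge = 12)
inst0 <- instrument_params(noise_sd = 0, n_replicates = 1)

test_that("species and instrument parameter invariants are enforced", {
  expect_error(species_params("x", 37, 34, 40, 0.8, mass = 1e4), "exceed")
  expect_error(species_params("x", 34, 37, 40, -1, mass = 1e4), "slope")
  expect_error(instrument_params(voltage_grid = c(30, 30, 40)), "increasing")
  expect_error(instrument_params(n_replicates = 0), "replicates")
})

test_that("noise-free ATDs sit at the calibrated conformer positions", {
  model <- calibration_model(inst0$cal_A, inst0$cal_X, inst0$edc_coefficient,
                             inst0$drift_gas_mass)
  a_low <- simulate_atd(apo, inst0, 25)
  cen <- centroid_ccs(atd_to_ccs(a_low, model, apo$mz, apo$charge, apo$mass))
  expect_equal(cen, apo$ccs_compact, tolerance = 1e-3)
  # at the midpoint the two component masses are equal, so the centroid is
  # the conformer average
  a_mid <- simulate_atd(apo, inst0, apo$v50_unfold)
  cen_mid <- centroid_ccs(atd_to_ccs(a_mid, model, apo$mz, apo$charge, apo$mass))
  expect_equal(cen_mid, (apo$ccs_compact + apo$ccs_extended) / 2,
               tolerance = 1e-3)
})

test_that("ATD simulation is deterministic in the seed", {
  instn <- instrument_params(noise_sd = 0.05, n_replicates = 1)
  a1 <- simulate_atd(apo, instn, 40, seed = 7)
  a2 <- simulate_atd(apo, instn, 40, seed = 7)
  a3 <- simulate_atd(apo, instn, 40, seed = 8)
  expect_identical(a1$intensity, a2$intensity)
  expect_false(identical(a1$intensity, a3$intensity))
  expect_true(all(a3$intensity >= 0))
})

test_that("simulate_dataset produces the full factorial with stored truth", {
  inst <- instrument_params(voltage_grid = seq(30, 50, 2), noise_sd = 0.02,
                            n_replicates = 2)
  sps <- eftu_species_defaults()
  ds <- simulate_dataset(sps, inst, seed = 11)
  expect_named(ds$atds, c("apo", "binary", "ternary"))
  expect_length(ds$atds$apo, 2)
  expect_equal(dim(ds$atds$ternary[[2]]),
               c(length(attr(ds$atds$ternary[[2]], "time")), 11))
  expect_identical(ds$truth$species, sps)
  ds2 <- simulate_dataset(sps, inst, seed = 11)
  expect_identical(ds$atds$apo[[1]][, 3], ds2$atds$apo[[1]][, 3])
  ds3 <- simulate_dataset(sps, inst, seed = 12)
  expect_false(identical(ds$atds$apo[[1]][, 3], ds3$atds$apo[[1]][, 3]))
  expect_identical(ds3$truth$species, ds$truth$species)
  expect_error(simulate_dataset(list(), inst), "non-empty")
})

test_that("noise-free centroid traces match the generative logistic", {
  inst <- instrument_params(noise_sd = 0, n_replicates = 1)
  ds <- simulate_dataset(list(apo), inst, seed = 1)
  model <- calibration_model(inst$cal_A, inst$cal_X, inst$edc_coefficient,
                             inst$drift_gas_mass)
  cv <- unfolding_curve(ds$atds$apo[[1]], model, apo$mz, apo$charge, apo$mass)
  f <- unfolded_fraction(cv$voltage, apo$v50_unfold, apo$slope_unfold)
  expected <- apo$ccs_compact + (apo$ccs_extended - apo$ccs_compact) * f
  expect_true(all(abs(cv$ccs / expected - 1) < 1e-3))
})

test_that("ejection coupling fades as the ligand is lost", {
  # ternary shares the binary baseline midpoint; at high voltage, where the
  # ligand is fully ejected, the two unfolded fractions must coincide
  inst <- instrument_params(noise_sd = 0, n_replicates = 1)
  tern <- eftu_species_defaults()[[3]]
  bare <- tern; bare$ejection <- NULL
  model <- calibration_model(inst$cal_A, inst$cal_X, inst$edc_coefficient,
                             inst$drift_gas_mass)
  cen <- function(sp, v) {
    centroid_ccs(atd_to_ccs(simulate_atd(sp, inst, v), model, sp$mz,
                            sp$charge, sp$mass))
  }
  expect_equal(cen(tern, 60), cen(bare, 60), tolerance = 1e-4)
  # while the ligand survives the ternary species is harder to unfold
  expect_lt(cen(tern, 42), cen(bare, 42))
})

test_that("simulated calibrants round-trip and flag short tables", {
  cal <- simulate_calibrants(0.8, 1.41, noise_sd = 0, seed = 1)
  m <- fit_calibration(cal)
  expect_equal(m$X, 1.41, tolerance = 1e-7)
  expect_equal(m$A, 0.8, tolerance = 1e-7)
  one <- read_calibrant_table()[1, ]
  short <- simulate_calibrants(0.8, 1.41, calibrant_specs = one)
  expect_true(isTRUE(attr(short, "insufficient_for_fit")))
  c1 <- simulate_calibrants(0.8, 1.41, noise_sd = 0.01, seed = 5)
  c2 <- simulate_calibrants(0.8, 1.41, noise_sd = 0.01, seed = 5)
  expect_identical(c1$td, c2$td)
})

test_that("self-avoiding walk structures obey their construction", {
  s1 <- simulate_structure(1)
  expect_equal(nrow(s1), 1)
  expect_equal(unlist(s1[1, c("x", "y", "z")]), c(x = 0, y = 0, z = 0))
  s <- simulate_structure(30, bond_length = 1.5, seed = 4)
  xyz <- as.matrix(s[, c("x", "y", "z")])
  steps <- sqrt(rowSums(diff(xyz)^2))
  expect_true(all(abs(steps - 1.5) < 1e-9))
  d <- as.matrix(dist(xyz))
  diag(d) <- Inf
  nonbonded <- d[abs(row(d) - col(d)) > 1]
  expect_true(all(nonbonded > 1.0))
  expect_identical(simulate_structure(30, seed = 4), s)
  expect_error(simulate_structure(0), "n_atoms")
})
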