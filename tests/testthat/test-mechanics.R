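test_that("compute_mechanics applies the bedside formulas", {
  m <- compute_mechanics(ppk = 30, pplat = 20, peep_tot = 10,
                         applied_peep = 0, tidal_volume = 0.5,
                         inspiratory_flow = 0.5)
  expect_equal(m$compliance, 0.05)
  expect_equal(m$elastance, 20)
  expect_equal(m$resistance, 20)
  expect_equal(m$auto_peep, 10)
  m2 <- compute_mechanics(30, 20, 10, applied_peep = 6, tidal_volume = 0.5,
                          inspiratory_flow = 0.5)
  expect_equal(m2$auto_peep, 4)
})

test_that("compute_mechanics averages triplicates and flags validity", {
  m <- compute_mechanics(c(29, 30, 31), c(19, 20, 21), c(9.5, 10, 10.5),
                         0, 0.5, 0.5)
  expect_equal(m$ppk, 30)
  expect_equal(m$auto_peep, 10)
  expect_true(m$valid)
  # a wildly discordant triplicate invalidates the measurement
  bad <- compute_mechanics(c(30, 30, 30), c(20, 20, 20), c(6, 10, 14),
                           0, 0.5, 0.5)
  expect_false(bad$valid)
})

test_that("degenerate and inconsistent pressure sets are rejected", {
  expect_error(compute_mechanics(30, 10, 12, 0, 0.5, 0.5), "degenerate")
  expect_error(compute_mechanics(30, 20, 2, 6, 0.5, 0.5), "inconsistent")
})

test_that("triplicate rule: <10% of the mean, 1 cmH2O always tolerated", {
  expect_true(validate_triplicate(c(18, 20, 22)))   # 2 < 10% of 20
  expect_false(validate_triplicate(c(8, 10, 12)))   # 2 > max(1, 1)
  expect_true(validate_triplicate(c(5, 5.9, 5.5)))  # within the 1 cmH2O floor
  expect_error(validate_triplicate(c(1, 2)), "three")
})

test_that("triplicate rule scales with the mean (relative branch)", {
  base <- c(18, 20, 22)
  expect_true(validate_triplicate(base))
  expect_true(validate_triplicate(base * 2))   # deviations scale with mean
  expect_false(validate_triplicate(c(17, 20, 23) / 2))
})

test_that("mechanics formulas recover generating R and E from waveforms", {
  R <- 18; C <- 1 / 19; raw <- 0
  model <- lung_model(list(lung_compartment(resistance = R, compliance = C)),
                      noise_sd = 0, airway_resistance = raw)
  s <- vent_settings(0.45, 14, 0.9)
  ss <- steady_state(model, s)
  rec <- simulate_breaths(model, s, 1, sample_rate = 100, state = ss$v_ee)
  ppk <- max(rec$paw)
  pplat <- measure_plateau(simulate_occlusion(model, s, ss$v_ei,
                                              "end_inspiratory"))
  peep_tot <- measure_plateau(simulate_occlusion(model, s, ss$v_ee,
                                                 "end_expiratory"))
  m <- compute_mechanics(ppk, pplat, peep_tot, 0, s$tidal_volume,
                         s$inspiratory_flow)
  expect_equal(m$resistance, R, tolerance = 0.05)
  expect_equal(m$elastance, 19, tolerance = 0.05)
})

test_that("measure_plateau rejects corrupted maneuvers", {
  model <- lung_model(list(lung_compartment(20, 0.05)), noise_sd = 0)
  s <- vent_settings(0.5, 15, 1)
  occ <- simulate_occlusion(model, s, steady_state(model, s)$v_ee,
                            "end_expiratory")
  occ$flow[10] <- 0.3   # leak during the occlusion
  expect_error(measure_plateau(occ), "corrupted")
  rec <- simulate_breaths(model, s, 2, sample_rate = 100)
  expect_error(measure_plateau(rec), "occlusion")
})

test_that("persistent expiratory flow at end-expiration is detected", {
  s <- vent_settings(0.5, 20, 1)
  trapped <- lung_model(list(lung_compartment(40, 0.06)), noise_sd = 0)
  rec <- simulate_breaths(trapped, s, 4, sample_rate = 100,
                          state = steady_state(trapped, s)$v_ee)
  expect_true(check_persistent_expiratory_flow(rec))
  free <- lung_model(list(lung_compartment(5, 0.04)), noise_sd = 0)
  rec2 <- simulate_breaths(free, s, 4, sample_rate = 100,
                           state = steady_state(free, s)$v_ee)
  expect_false(check_persistent_expiratory_flow(rec2))
  expect_error(check_persistent_expiratory_flow(
    simulate_breaths(free, s, 2, sample_rate = 100)), "three")
})
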