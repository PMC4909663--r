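# Closed-form oracle for a single non-flow-limited compartment at steady
# state: auto-PEEP = (VT/C) / (exp(Te/RC) - 1).
oracle_autopeep <- function(vt, C, R, te) (vt / C) / (expm1(te / (R * C)))

single_model <- function(R, C, noise_sd = 0) {
  lung_model(list(lung_compartment(resistance = R, compliance = C)),
             noise_sd = noise_sd)
}

test_that("steady-state auto-PEEP matches the closed-form oracle", {
  s <- vent_settings(0.5, 15, 1)   # Te = 3 s
  ss <- steady_state(single_model(20, 0.05), s)
  expect_equal(ss$auto_peep, oracle_autopeep(0.5, 0.05, 20, 3),
               tolerance = 1e-6)
})

test_that("auto-PEEP vanishes when expiration is long enough", {
  s <- vent_settings(0.5, 4, 1)    # Te = 14 s >> tau = 0.5 s
  ss <- steady_state(single_model(10, 0.05), s)
  expect_lt(ss$auto_peep, 1e-6)
})

test_that("auto-PEEP is monotone increasing in resistance", {
  s <- vent_settings(0.5, 18, 1)
  aps <- vapply(c(5, 10, 20, 40),
                function(R) steady_state(single_model(R, 0.05), s)$auto_peep, 0)
  expect_true(all(diff(aps) > 0))
})

test_that("rendered breaths conserve mass at steady state", {
  model <- single_model(20, 0.05)
  s <- vent_settings(0.5, 15, 1)
  ss <- steady_state(model, s)
  rec <- simulate_breaths(model, s, n_breaths = 3, sample_rate = 200,
                          state = ss$v_ee)
  dt <- 1 / rec$sample_rate
  inspired <- sum(rec$flow[rec$phase == "insp"]) * dt
  expired <- -sum(rec$flow[rec$phase == "exp"]) * dt
  expect_equal(inspired / 3, 0.5, tolerance = 0.01)
  expect_equal(expired, inspired, tolerance = 0.02)
  # the end-expiratory state returns to itself
  expect_equal(sum(attr(rec, "v_end")), sum(ss$v_ee), tolerance = 1e-6)
})

test_that("applied PEEP shifts a non-FL system without changing auto-PEEP", {
  model <- single_model(25, 0.06)
  s <- vent_settings(0.5, 18, 1)
  ss0 <- steady_state(model, set_applied_peep(s, 0))
  ss6 <- steady_state(model, set_applied_peep(s, 6))
  expect_equal(ss6$palv_ee, ss0$palv_ee + 6, tolerance = 1e-6)
  expect_equal(ss6$auto_peep, ss0$auto_peep, tolerance = 1e-6)
  expect_equal(ss6$peep_tot, ss0$peep_tot + 6, tolerance = 1e-6)
})

test_that("a fully flow-limited system absorbs applied PEEP completely", {
  # envelope flow is independent of downstream pressure, so expiration and
  # hence end-expiratory alveolar pressure are unchanged by the PEEP
  model <- lung_model(list(
    lung_compartment(resistance = 15, compliance = 0.05, flow_limited = TRUE,
                     envelope_slope = 0.2)), noise_sd = 0)
  s <- vent_settings(0.5, 15, 1)
  ss0 <- steady_state(model, set_applied_peep(s, 0))
  applied <- round(0.8 * ss0$auto_peep)
  ss1 <- steady_state(model, set_applied_peep(s, applied))
  expect_gt(ss0$auto_peep, 5)
  expect_equal(ss1$peep_tot, ss0$peep_tot, tolerance = 1e-3)
})

test_that("end-expiratory occlusion equilibrates to the compliance-weighted mean", {
  s <- vent_settings(0.5, 15, 1)
  model <- lung_model(list(
    lung_compartment(resistance = 10, compliance = 0.02, volume_share = 0.4),
    lung_compartment(resistance = 30, compliance = 0.03, volume_share = 0.6)),
    noise_sd = 0)
  # start the occlusion from hand-picked regional volumes: P = 4 and 10
  v <- c(0.02 * 4, 0.03 * 10)
  occ <- simulate_occlusion(model, s, v, "end_expiratory", duration = 4,
                            sample_rate = 100)
  expect_true(all(abs(occ$flow) < 1e-9))
  plateau <- measure_plateau(occ)
  expect_equal(as.numeric(plateau),
               (0.02 * 4 + 0.03 * 10) / 0.05, tolerance = 0.01)
  expect_true(attr(plateau, "converged"))
})

test_that("sampling that cannot resolve the fastest compartment errors", {
  model <- lung_model(list(lung_compartment(resistance = 0.5,
                                            compliance = 0.01)))
  s <- vent_settings(0.5, 15, 1)
  expect_error(simulate_breaths(model, s, 2, sample_rate = 50),
               "step-size")
})

test_that("waveform simulation is reproducible under a seed", {
  model <- single_model(20, 0.05, noise_sd = 0.2)
  s <- vent_settings(0.5, 15, 1)
  a <- simulate_breaths(model, s, 3, sample_rate = 100, seed = 11)
  b <- simulate_breaths(model, s, 3, sample_rate = 100, seed = 11)
  expect_identical(a$paw, b$paw)
  expect_identical(a$flow, b$flow)
})

test_that("two-compartment calibration hits both regional auto-PEEP targets", {
  s <- vent_settings(0.5, 15, 1)
  m <- calibrate_fig2_patient(4, 10, settings = s)
  ss <- steady_state(m, s)
  expect_equal(ss$auto_peep_compartments[1], 4, tolerance = 0.05)
  expect_equal(ss$auto_peep_compartments[2], 10, tolerance = 0.05)
  # symmetric targets are also reachable
  m2 <- calibrate_fig2_patient(5, 5, settings = s)
  ss2 <- steady_state(m2, s)
  expect_equal(unname(ss2$auto_peep_compartments), c(5, 5), tolerance = 0.05)
})

test_that("compression expels more volume than passive expiration off the envelope", {
  model <- single_model(20, 0.05)
  s <- vent_settings(0.5, 15, 1)
  ss <- steady_state(model, s)
  pair <- simulate_compression(model, s, ss$v_ei, delta_pressure = 10,
                               sample_rate = 100)
  dt <- 1 / pair$passive$sample_rate
  expect_gt(-sum(pair$compressed$flow) * dt, -sum(pair$passive$flow) * dt)
})
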