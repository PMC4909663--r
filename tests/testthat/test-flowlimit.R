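exp_segment <- function(model, settings, delta = 0) {
  ss <- steady_state(model, settings)
  pair <- simulate_compression(model, settings, ss$v_ei,
                               delta_pressure = max(delta, 1e-9) + 1e-9,
                               sample_rate = 200)
  if (delta > 0) pair$compressed else pair$passive
}

test_that("build_loop reproduces the analytic RC flow-volume relation", {
  # passive single-compartment expiration: flow(v expired) = (V0 - v) / tau
  R <- 20; C <- 0.05; tau <- R * C
  model <- lung_model(list(lung_compartment(R, C)), noise_sd = 0)
  s <- vent_settings(0.5, 15, 1)
  ss <- steady_state(model, s)
  loop <- build_loop(exp_segment(model, s))
  v0 <- sum(ss$v_ei)
  keep <- loop$expired_volume < 0.9 * max(loop$expired_volume)
  expect_equal(loop$expiratory_flow[keep],
               (v0 - loop$expired_volume[keep]) / tau,
               tolerance = 0.02)
})

test_that("identical loops are superimposed; a scaled loop is not", {
  grid <- seq(0, 0.5, length.out = 200)
  mk <- function(scale) structure(list(expired_volume = grid,
                                       expiratory_flow = scale * (0.6 - grid),
                                       maneuver_id = 1L),
                                  class = "flow_volume_loop")
  same <- detect_flow_limitation(mk(1), mk(1))
  expect_true(same$flow_limited)
  expect_equal(same$superimposed_fraction, 1)
  scaled <- detect_flow_limitation(mk(1), mk(1.5))
  expect_false(scaled$flow_limited)
})

test_that("non-FL compartments separate under compression; FL ones superimpose", {
  s <- vent_settings(0.5, 15, 1)
  nfl <- lung_model(list(lung_compartment(25, 0.05)), noise_sd = 0)
  det_n <- detect_flow_limitation(build_loop(exp_segment(nfl, s)),
                                  build_loop(exp_segment(nfl, s, delta = 10)))
  expect_false(det_n$flow_limited)
  fl <- lung_model(list(lung_compartment(15, 0.05, flow_limited = TRUE,
                                         envelope_slope = 0.25)), noise_sd = 0)
  det_f <- detect_flow_limitation(build_loop(exp_segment(fl, s)),
                                  build_loop(exp_segment(fl, s, delta = 10)))
  expect_true(det_f$flow_limited)
  expect_gt(det_f$superimposed_fraction, 0.8)
})

test_that("a mixed patient superimposes over part of the loop only", {
  s <- vent_settings(0.5, 15, 1)
  mixed <- lung_model(list(
    lung_compartment(40, 0.015, volume_share = 0.3),
    lung_compartment(15, 0.035, flow_limited = TRUE, envelope_slope = 0.25,
                     volume_share = 0.7)), noise_sd = 0)
  det <- detect_flow_limitation(build_loop(exp_segment(mixed, s)),
                                build_loop(exp_segment(mixed, s, delta = 10)))
  expect_gt(det$superimposed_fraction, 0.1)
  expect_lt(det$superimposed_fraction, 0.999)
})

test_that("zero-flow and non-monotone segments are rejected", {
  dead <- new_recording(time = seq(0.01, 1, by = 0.01),
                        paw = rep(0, 100), flow = rep(0, 100),
                        volume = rep(0, 100), phase = rep("exp", 100),
                        sample_rate = 100)
  expect_error(build_loop(dead), "zero-flow")
  insp <- dead; insp$phase <- rep("insp", 100)
  expect_error(build_loop(insp), "no expiratory")
  wob <- dead
  wob$flow <- -sin(seq(0, 4 * pi, length.out = 100)) # inspiratory swings
  expect_error(build_loop(wob), "monotone")
})

test_that("the verdict is invariant to grid refinement", {
  s <- vent_settings(0.5, 15, 1)
  fl <- lung_model(list(lung_compartment(15, 0.05, flow_limited = TRUE,
                                         envelope_slope = 0.25)), noise_sd = 0)
  p <- exp_segment(fl, s); c_ <- exp_segment(fl, s, delta = 10)
  d1 <- detect_flow_limitation(build_loop(p, n_grid = 100),
                               build_loop(c_, n_grid = 100), n_grid = 100)
  d2 <- detect_flow_limitation(build_loop(p, n_grid = 400),
                               build_loop(c_, n_grid = 400), n_grid = 400)
  expect_identical(d1$flow_limited, d2$flow_limited)
  expect_equal(d1$superimposed_fraction, d2$superimposed_fraction,
               tolerance = 0.05)
})

test_that("patient-level classification needs all three maneuvers positive", {
  expect_true(classify_patient_fl(c(TRUE, TRUE, TRUE)))
  expect_false(classify_patient_fl(c(TRUE, FALSE, TRUE)))
  expect_error(classify_patient_fl(c(TRUE, TRUE)), "three")
  dets <- replicate(3, list(flow_limited = TRUE, superimposed_fraction = 1),
                    simplify = FALSE)
  expect_true(classify_patient_fl(dets))
})
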