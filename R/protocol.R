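#' Measurement-protocol configuration
#'
#' Defaults mirror the study protocol: triplicate 4-s end-inspiratory and
#' end-expiratory occlusions with at least ten uninterrupted breaths between
#' maneuvers, three abdominal-compression maneuvers, then PEEP set to 80 %
#' of the auto-PEEP measured at ZEEP and the measurements repeated.
#'
#' @param occlusion_duration Occlusion length, s.
#' @param n_repeats Repetitions of each maneuver.
#' @param interleave_breaths Uninterrupted breaths between maneuvers.
#' @param peep_fraction Fraction of ZEEP auto-PEEP applied as PEEP.
#' @param enrollment_threshold Minimum auto-PEEP at ZEEP, cmH2O.
#' @param compression_delta Abdominal-compression pressure, cmH2O.
#' @param sample_rate Waveform sampling rate, Hz.
#' @param plateau_window Plateau averaging window, s.
#' @param zero_flow_tol Zero-flow tolerance, L/s.
#' @param fl_tol_abs,fl_tol_rel,fl_min_fraction Loop-superposition detector
#'   tolerances (see [detect_flow_limitation()]).
#' @param detail `"fast"` computes maneuver readings from the closed-form
#'   state (adding measurement noise equivalent to reading the rendered
#'   waveforms); `"waveforms"` renders and processes every maneuver segment.
#' @return A named list of protocol options.
#' @export
protocol_config <- function(occlusion_duration = 4, n_repeats = 3,
                            interleave_breaths = 10, peep_fraction = 0.8,
                            enrollment_threshold = 5, compression_delta = 10,
                            sample_rate = 100, plateau_window = 0.5,
                            zero_flow_tol = 0.02, fl_tol_abs = 0.02,
                            fl_tol_rel = 0.05, fl_min_fraction = 0.20,
                            detail = c("fast", "waveforms")) {
  list(occlusion_duration = occlusion_duration, n_repeats = n_repeats,
       interleave_breaths = interleave_breaths, peep_fraction = peep_fraction,
       enrollment_threshold = enrollment_threshold,
       compression_delta = compression_delta, sample_rate = sample_rate,
       plateau_window = plateau_window, zero_flow_tol = zero_flow_tol,
       fl_tol_abs = fl_tol_abs, fl_tol_rel = fl_tol_rel,
       fl_min_fraction = fl_min_fraction, detail = match.arg(detail))
}

# Triplicate maneuver readings for one phase. In fast detail the plateau
# reading is the true equilibrated pressure plus the noise of averaging
# `plateau_window` seconds of sensor samples; Ppk is a single noisy sample.
phase_measurements <- function(model, settings, config) {
  pars <- model_pars(model)
  ss <- steady_state(model, settings)
  q <- settings$inspiratory_flow
  wC <- pars$C / sum(pars$C)
  r_insp <- pars$Raw + sum(wC * pars$w * pars$R)
  true_ppk <- q * r_insp + ss$pstar_ei
  nrep <- config$n_repeats
  if (config$detail == "fast") {
    n_win <- max(2, round(config$plateau_window * config$sample_rate))
    sd_plat <- model$noise_sd / sqrt(n_win)
    ppk <- true_ppk + stats::rnorm(nrep, 0, model$noise_sd)
    pplat <- ss$pstar_ei + stats::rnorm(nrep, 0, sd_plat)
    peep_tot <- ss$pstar_ee + stats::rnorm(nrep, 0, sd_plat)
    segs <- NULL
  } else {
    ppk <- pplat <- peep_tot <- numeric(nrep)
    segs <- list()
    for (r in seq_len(nrep)) {
      breaths <- simulate_breaths(model, settings,
                                  n_breaths = max(3, config$interleave_breaths),
                                  sample_rate = config$sample_rate,
                                  state = ss$v_ee)
      insp <- breaths$phase == "insp"
      ppk[r] <- max(breaths$paw[insp])
      occ_ei <- simulate_occlusion(model, settings, ss$v_ei, "end_inspiratory",
                                   config$occlusion_duration, config$sample_rate)
      occ_ee <- simulate_occlusion(model, settings, ss$v_ee, "end_expiratory",
                                   config$occlusion_duration, config$sample_rate)
      pplat[r] <- measure_plateau(occ_ei, config$plateau_window,
                                  config$zero_flow_tol)
      peep_tot[r] <- measure_plateau(occ_ee, config$plateau_window,
                                     config$zero_flow_tol)
      segs[[r]] <- list(breaths = breaths, occl_insp = occ_ei, occl_exp = occ_ee)
    }
  }
  mech <- compute_mechanics(ppk, pplat, peep_tot, settings$applied_peep,
                            settings$tidal_volume, settings$inspiratory_flow)
  list(mechanics = mech, state = ss, segments = segs)
}

fl_assessment <- function(model, settings, config) {
  ss <- steady_state(model, settings)
  out <- vector("list", config$n_repeats)
  for (r in seq_len(config$n_repeats)) {
    pair <- simulate_compression(model, settings, ss$v_ei,
                                 delta_pressure = config$compression_delta,
                                 sample_rate = config$sample_rate)
    det <- detect_flow_limitation(build_loop(pair$passive, maneuver_id = r),
                                  build_loop(pair$compressed, maneuver_id = r),
                                  tol_abs = config$fl_tol_abs,
                                  tol_rel = config$fl_tol_rel,
                                  min_fraction = config$fl_min_fraction)
    out[[r]] <- det
  }
  list(flow_limited = classify_patient_fl(out),
       fractions = vapply(out, `[[`, 0, "superimposed_fraction"),
       maneuvers = out)
}

#' Run the full pre-post measurement protocol on one simulated patient
#'
#' Stabilizes the patient at ZEEP, performs triplicate occlusion
#' measurements and the three abdominal-compression maneuvers, applies PEEP
#' equal to 80 % of the measured auto-PEEP (rounded to an integer), lets the
#' ventilation re-stabilize and repeats the occlusion measurements; finally
#' classifies the PEEP-absorber behaviour.
#'
#' @param model A [lung_model()].
#' @param settings A [vent_settings()]; its applied PEEP is forced to 0 for
#'   the baseline phase.
#' @param config A [protocol_config()].
#' @param seed Optional integer seed (all measurement noise flows from it).
#' @return A list of class `protocol_result`: `eligible`, `valid`,
#'   `flow_limited`, `applied_peep`, `measurements`
#'   (a [study_measurements()] object when eligible), `classification`, and
#'   (with `detail = "waveforms"`) the raw segments.
#' @export
run_protocol <- function(model, settings, config = protocol_config(),
                         seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  settings0 <- set_applied_peep(settings, 0)
  zeep <- phase_measurements(model, settings0, config)
  fl <- fl_assessment(model, settings0, config)
  auto_peep_zeep <- zeep$mechanics$auto_peep
  if (auto_peep_zeep < config$enrollment_threshold) {
    return(structure(list(
      eligible = FALSE, valid = zeep$mechanics$valid,
      flow_limited = fl$flow_limited, auto_peep_zeep = auto_peep_zeep,
      applied_peep = NA_real_, measurements = NULL, classification = NULL,
      zeep = zeep$mechanics, fl_detail = fl
    ), class = "protocol_result"))
  }
  applied <- applied_peep_from_autopeep(auto_peep_zeep, config$peep_fraction,
                                        config$enrollment_threshold)
  settings1 <- set_applied_peep(settings, applied)
  peep <- phase_measurements(model, settings1, config)
  meas <- study_measurements(zeep$mechanics, peep$mechanics, applied,
                             fl = fl$flow_limited)
  cls <- classify_absorber(meas)
  structure(list(
    eligible = TRUE,
    valid = zeep$mechanics$valid && peep$mechanics$valid,
    flow_limited = fl$flow_limited,
    auto_peep_zeep = auto_peep_zeep,
    applied_peep = applied,
    measurements = meas,
    classification = cls,
    zeep = zeep$mechanics, peep = peep$mechanics, fl_detail = fl,
    segments = if (config$detail == "waveforms") {
      list(zeep = zeep$segments, peep = peep$segments)
    }
  ), class = "protocol_result")
}

#' @export
print.protocol_result <- function(x, ...) {
  if (!x$eligible) {
    cat(sprintf("Ineligible patient: auto-PEEP %.1f cmH2O at ZEEP\n",
                x$auto_peep_zeep))
    return(invisible(x))
  }
  cat(sprintf(
    "Protocol: auto-PEEP %.1f -> applied PEEP %d; PEEPtot %.1f -> %.1f (d %.2f, %.0f%% of applied)\n",
    x$auto_peep_zeep, x$applied_peep, x$zeep$peep_tot, x$peep$peep_tot,
    x$measurements$delta_peep_tot, x$classification$delta_percent_of_applied))
  cat(sprintf("  flow limited: %s; label: %s; triplicates valid: %s\n",
              x$flow_limited, as.character(x$classification$label), x$valid))
  invisible(x)
}
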