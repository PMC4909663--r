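#' Read an occlusion plateau pressure from a waveform segment
#'
#' Mean airway pressure over the final `window` seconds of an occlusion
#' segment. The maneuver is rejected if airway flow is not zero (within the
#' zero-flow tolerance) throughout the occlusion; a non-convergence flag is
#' attached when the pressure still drifts by more than 0.05 cmH2O/s over
#' the averaging window.
#'
#' @param segment A [waveform_recording] occlusion segment (phase
#'   `occl_insp` or `occl_exp`).
#' @param window Averaging window in seconds (default 0.5).
#' @param zero_flow_tol Zero-flow tolerance in L/s (default 0.02).
#' @return Plateau pressure in cmH2O, with attribute `converged`.
#' @export
measure_plateau <- function(segment, window = 0.5, zero_flow_tol = 0.02) {
  stopifnot(inherits(segment, "waveform_recording"))
  if (!all(segment$phase %in% c("occl_insp", "occl_exp"))) {
    stop("segment is not annotated as an occlusion", call. = FALSE)
  }
  n <- length(segment$time)
  if (window > n / segment$sample_rate) {
    stop("window longer than the occlusion segment", call. = FALSE)
  }
  if (any(abs(segment$flow) > zero_flow_tol)) {
    stop("corrupted maneuver: airway flow exceeds the zero-flow tolerance ",
         "during the occlusion", call. = FALSE)
  }
  n_win <- max(2L, round(window * segment$sample_rate))
  idx <- (n - n_win + 1):n
  slope <- stats::coef(stats::lm(segment$paw[idx] ~ segment$time[idx]))[[2]]
  out <- mean(segment$paw[idx])
  attr(out, "converged") <- abs(slope) <= 0.05
  out
}

#' Respiratory-system mechanics from occlusion pressures
#'
#' Applies the bedside formulas: compliance = VT / (Pplat - PEEPtot),
#' resistance = (Ppk - Pplat) / inspiratory flow, and
#' auto-PEEP = PEEPtot - applied PEEP. Inputs may be triplicate vectors (the
#' protocol repeats each maneuver three times); means are used for the
#' derived quantities and the triplicate repeatability rule decides
#' validity.
#'
#' @param ppk Peak airway pressure(s), cmH2O.
#' @param pplat End-inspiratory plateau pressure(s), cmH2O.
#' @param peep_tot End-expiratory occlusion plateau pressure(s), cmH2O.
#' @param applied_peep Applied PEEP, cmH2O.
#' @param tidal_volume Tidal volume, L.
#' @param inspiratory_flow Constant inspiratory flow, L/s.
#' @return An object of class `mechanics_measurement`.
#' @examples
#' m <- compute_mechanics(30, 20, 10, 0, 0.5, 0.5)
#' m$compliance   # 0.05 L/cmH2O
#' m$resistance   # 20 cmH2O.s/L
#' m$auto_peep    # 10 cmH2O
#' @export
compute_mechanics <- function(ppk, pplat, peep_tot, applied_peep,
                              tidal_volume, inspiratory_flow) {
  stopifnot(inspiratory_flow > 0, tidal_volume > 0)
  mppk <- mean(ppk); mpplat <- mean(pplat); mpeep <- mean(peep_tot)
  if (mpplat <= mpeep) {
    stop("degenerate mechanics: Pplat (", signif(mpplat, 4),
         ") must exceed PEEPtot (", signif(mpeep, 4), ")", call. = FALSE)
  }
  auto_peep <- mpeep - applied_peep
  if (auto_peep < -0.5) {
    stop("inconsistent inputs: PEEPtot below applied PEEP (auto-PEEP ",
         signif(auto_peep, 3), " cmH2O)", call. = FALSE)
  }
  compliance <- tidal_volume / (mpplat - mpeep)
  valid <- length(ppk) == 3 && length(pplat) == 3 && length(peep_tot) == 3 &&
    validate_triplicate(ppk) && validate_triplicate(pplat) &&
    validate_triplicate(peep_tot)
  structure(list(
    ppk = mppk, pplat = mpplat, peep_tot = mpeep,
    ppk_reps = ppk, pplat_reps = pplat, peep_tot_reps = peep_tot,
    applied_peep = applied_peep,
    auto_peep = max(auto_peep, 0),
    compliance = compliance,
    elastance = 1 / compliance,
    resistance = (mppk - mpplat) / inspiratory_flow,
    valid = valid
  ), class = "mechanics_measurement")
}

#' @export
print.mechanics_measurement <- function(x, ...) {
  cat(sprintf(
    "Mechanics: Ppk %.1f, Pplat %.1f, PEEPtot %.1f (applied %.1f, auto-PEEP %.1f) cmH2O\n",
    x$ppk, x$pplat, x$peep_tot, x$applied_peep, x$auto_peep))
  cat(sprintf("  C %.4f L/cmH2O (E %.1f), R %.1f cmH2O.s/L, valid: %s\n",
              x$compliance, x$elastance, x$resistance, x$valid))
  invisible(x)
}

#' Triplicate repeatability rule
#'
#' A triplet of pressure measurements is reliable when no value deviates
#' from the triplet mean by more than 10 % of that mean, with an absolute
#' difference of 1 cmH2O always tolerated.
#'
#' @param values Exactly three pressures (cmH2O).
#' @return `TRUE` or `FALSE`.
#' @examples
#' validate_triplicate(c(18, 20, 22))  # TRUE: 2 < 10 % of 20
#' validate_triplicate(c(8, 10, 12))   # FALSE: 2 > max(1, 1)
#' @export
validate_triplicate <- function(values) {
  if (length(values) != 3) stop("exactly three values required", call. = FALSE)
  m <- mean(values)
  all(abs(values - m) <= pmax(0.10 * m, 1))
}

#' Persistence of expiratory flow at the start of inspiration
#'
#' The inclusion screen for dynamic hyperinflation: expiration must still be
#' ongoing when the next insufflation starts, in every breath.
#'
#' @param recording A [waveform_recording] with at least three complete
#'   breaths (phases `insp`/`exp`).
#' @param zero_flow_tol Flow threshold in L/s (default 0.02).
#' @return `TRUE` when |flow| immediately before each inspiration exceeds
#'   the tolerance in every breath.
#' @export
check_persistent_expiratory_flow <- function(recording, zero_flow_tol = 0.02) {
  stopifnot(inherits(recording, "waveform_recording"))
  ph <- recording$phase
  # last expiratory sample of each breath = exp sample followed by insp (or end)
  ends <- which(ph == "exp" & c(ph[-1] == "insp", TRUE))
  if (length(ends) < 3) {
    stop("at least three steady-state breaths required", call. = FALSE)
  }
  all(abs(recording$flow[ends]) > zero_flow_tol)
}
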