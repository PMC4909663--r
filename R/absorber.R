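round_half_up <- function(x) floor(x + 0.5)

#' PEEP titration rule: 80 % of auto-PEEP at ZEEP
#'
#' The protocol applies a PEEP equal to 80 % of the auto-PEEP measured at
#' ZEEP, rounded to the nearest ventilator-settable integer (ties upward).
#' Patients below the enrollment threshold are signalled as ineligible.
#'
#' @param auto_peep_zeep Auto-PEEP measured at ZEEP, cmH2O.
#' @param fraction Fraction of auto-PEEP to apply (default 0.8).
#' @param threshold Enrollment threshold in cmH2O (default 5).
#' @return Applied PEEP in integer cmH2O.
#' @examples
#' applied_peep_from_autopeep(7)   # 6 (0.8 * 7 = 5.6)
#' applied_peep_from_autopeep(10)  # 8
#' @export
applied_peep_from_autopeep <- function(auto_peep_zeep, fraction = 0.8,
                                       threshold = 5) {
  if (auto_peep_zeep < threshold) {
    stop(structure(class = c("peep_ineligible", "error", "condition"),
                   list(message = paste0("ineligible: auto-PEEP ",
                                         signif(auto_peep_zeep, 3),
                                         " cmH2O below the enrollment threshold ",
                                         threshold, " cmH2O"),
                        call = sys.call(-1))))
  }
  round_half_up(fraction * auto_peep_zeep)
}

#' Pre-post study measurements for one patient
#'
#' Couples the ZEEP and PEEP-phase mechanics with the flow-limitation
#' verdict and the change in total PEEP.
#'
#' @param zeep,peep_phase [compute_mechanics()] results at ZEEP and after
#'   PEEP application.
#' @param applied_peep Applied PEEP, cmH2O.
#' @param fl Patient-level flow-limitation classification (logical).
#' @return An object of class `study_measurements`.
#' @export
study_measurements <- function(zeep, peep_phase, applied_peep, fl = NA) {
  stopifnot(inherits(zeep, "mechanics_measurement"),
            inherits(peep_phase, "mechanics_measurement"))
  if (abs(zeep$applied_peep) > 1e-9) {
    stop("baseline phase must be at ZEEP", call. = FALSE)
  }
  delta <- peep_phase$peep_tot - zeep$peep_tot
  structure(list(
    zeep = zeep, peep_phase = peep_phase, applied_peep = applied_peep,
    fl = fl, delta_peep_tot = delta,
    delta_percent_of_applied = if (applied_peep > 0) 100 * delta / applied_peep else NA_real_
  ), class = "study_measurements")
}

#' Classify PEEP-absorber behaviour
#'
#' Total PEEP is considered unchanged when it rises by at most 1 cmH2O
#' (the accuracy of the pressure measurement): such patients are "complete
#' PEEP-absorbers" (a fall in total PEEP also qualifies). Otherwise the
#' patient is a "high PEEP-absorber" when the rise is less than 50 % of the
#' applied PEEP (strictly), and a "low PEEP-absorber" otherwise.
#'
#' @param measurements A [study_measurements()] object, or a bare
#'   ΔPEEPtot value in cmH2O if `applied_peep` is also given.
#' @param applied_peep Applied PEEP in cmH2O (when `measurements` is bare).
#' @return A list with `label` (factor: complete/high/low) and
#'   `delta_percent_of_applied`.
#' @examples
#' classify_absorber(1.0, applied_peep = 5)$label  # complete (boundary in)
#' classify_absorber(2.0, applied_peep = 5)$label  # high (2 < 2.5)
#' classify_absorber(2.5, applied_peep = 5)$label  # low (not < 50 %)
#' @export
classify_absorber <- function(measurements, applied_peep = NULL) {
  if (inherits(measurements, "study_measurements")) {
    delta <- measurements$delta_peep_tot
    applied_peep <- measurements$applied_peep
    if (!(isTRUE(measurements$zeep$valid) && isTRUE(measurements$peep_phase$valid))) {
      warning("triplicate validation failed in at least one phase", call. = FALSE)
    }
  } else {
    delta <- measurements
  }
  if (is.null(applied_peep) || applied_peep <= 0) {
    stop("undefined percentage: applied_peep must be > 0", call. = FALSE)
  }
  label <- if (delta <= 1) "complete"
           else if (delta < 0.5 * applied_peep) "high"
           else "low"
  list(label = factor(label, levels = c("complete", "high", "low")),
       delta_peep_tot = delta,
       delta_percent_of_applied = 100 * delta / applied_peep)
}

#' Cohort-level summary of PEEP-absorber behaviour
#'
#' Class fractions, the distribution of ΔPEEPtot (absolute and as % of
#' applied PEEP), and per-class covariate summaries (mean ± SD for numeric
#' covariates, count (%) for binary ones).
#'
#' @param labels Factor/character vector of absorber labels.
#' @param deltas ΔPEEPtot values, cmH2O.
#' @param applied Applied PEEP values, cmH2O.
#' @param covariates Optional data frame of per-patient covariates.
#' @return A list with `fractions`, `counts`, `delta_hist` /
#'   `delta_pct_hist` (histogram data), and `by_class` summaries.
#' @export
summarize_cohort <- function(labels, deltas, applied, covariates = NULL) {
  if (length(labels) == 0) stop("non-empty cohort required", call. = FALSE)
  labels <- factor(labels, levels = c("complete", "high", "low"))
  counts <- table(labels)
  fractions <- as.numeric(counts) / length(labels)
  names(fractions) <- names(counts)
  delta_pct <- 100 * deltas / applied
  by_class <- NULL
  if (!is.null(covariates)) {
    num <- vapply(covariates, is.numeric, TRUE)
    by_class <- lapply(split(covariates, labels), function(d) {
      if (nrow(d) == 0) return(NULL)
      c(lapply(d[num], function(x) c(mean = mean(x), sd = stats::sd(x))),
        lapply(d[!num], function(x) {
          x <- as.logical(x); c(n = sum(x), pct = 100 * mean(x))
        }))
    })
  }
  list(n = length(labels), counts = as.vector(counts), fractions = fractions,
       delta_hist = graphics::hist(deltas, breaks = seq(floor(min(deltas, 0)),
                                                        ceiling(max(deltas, 1)), by = 1),
                                   plot = FALSE),
       delta_pct_hist = graphics::hist(delta_pct,
                                       breaks = pretty(c(delta_pct, 0, 100), 12),
                                       plot = FALSE),
       by_class = by_class)
}
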