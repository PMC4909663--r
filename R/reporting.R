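#' Run configuration for the command-line workflows
#'
#' Reads a YAML configuration file when one is given (requires the
#' optional `yaml` package); otherwise returns the defaults. Recognized
#' fields: `n_patients`, `seed`, `out_dir`, `waveform_patients` (how many
#' patients get full waveform CSV exports).
#'
#' @param path Optional YAML file path.
#' @return A named list of run options.
#' @export
run_config <- function(path = NULL) {
  cfg <- list(n_patients = 100, seed = 1, out_dir = ".",
              waveform_patients = 1)
  if (!is.null(path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading a config file requires the yaml package", call. = FALSE)
    }
    user <- yaml::read_yaml(path)
    bad <- setdiff(names(user), names(cfg))
    if (length(bad) > 0) {
      stop("unknown run_config field: ", bad[1], call. = FALSE)
    }
    cfg[names(user)] <- user
  }
  cfg
}

#' Simulate a study cohort and write it to disk
#'
#' Generates the cohort, runs the full measurement protocol on every
#' patient, writes the analysis dataset (`cohort.csv`), per-patient
#' waveform CSVs for the first `waveform_patients` patients
#' (steady-state breaths at ZEEP), and a `manifest.json` describing the
#' run.
#'
#' @param out_dir Output directory (created if absent).
#' @param n Number of patients.
#' @param seed Integer seed.
#' @param waveform_patients Number of patients with waveform exports.
#' @param cohort_cfg A [cohort_config()].
#' @param protocol_cfg A [protocol_config()].
#' @return The manifest list, invisibly.
#' @export
cmd_simulate <- function(out_dir, n = 100, seed = 1, waveform_patients = 1,
                         cohort_cfg = cohort_config(),
                         protocol_cfg = protocol_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- generate_cohort(n, cohort_cfg, seed = seed)
  study <- run_study(cohort, protocol_cfg, seed = seed)
  cohort_path <- file.path(out_dir, "cohort.csv")
  write_cohort_csv(study, cohort_path)
  wf_files <- character(0)
  for (i in seq_len(min(waveform_patients, n))) {
    ss <- steady_state(cohort$models[[i]], cohort$settings[[i]])
    rec <- simulate_breaths(cohort$models[[i]], cohort$settings[[i]],
                            n_breaths = 3,
                            sample_rate = protocol_cfg$sample_rate,
                            seed = sub_seed(seed, i), state = ss$v_ee)
    p <- file.path(out_dir, sprintf("waveform_patient%03d.csv", i))
    write_waveform_csv(rec, p)
    wf_files <- c(wf_files, basename(p))
  }
  manifest <- list(n_patients = n, seed = seed,
                   cohort_file = basename(cohort_path),
                   waveform_files = wf_files,
                   eligible = sum(study$data$eligible),
                   created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA),
             file.path(out_dir, "manifest.json"))
  invisible(manifest)
}

# Characteristics-by-class table: mean (SD) for numeric covariates,
# n (%) for binary ones, plus the class comparison p-value.
characteristics_table <- function(data, covariates) {
  comp <- group_comparisons(data, covariates)
  lab <- factor(data$label, levels = c("complete", "high", "low"))
  rows <- lapply(covariates, function(nm) {
    x <- data[[nm]]
    cells <- vapply(levels(lab), function(l) {
      xi <- x[lab == l]
      if (is.logical(x) || length(unique(x)) <= 2) {
        sprintf("%d (%.0f%%)", sum(as.logical(xi)), 100 * mean(as.logical(xi)))
      } else {
        sprintf("%.1f (%.1f)", mean(as.numeric(xi)), stats::sd(as.numeric(xi)))
      }
    }, "")
    c(covariate = nm, cells,
      p_value = sprintf("%.3g", comp$p_value[comp$covariate == nm]))
  })
  as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
}

#' Analyze a simulated study dataset
#'
#' Reproduces the study's analysis on a dataset produced by
#' [cmd_simulate()] / [run_study()]: class counts and histograms of the
#' change in total PEEP, the characteristics-by-class table, the
#' univariate screen and pruned multivariable model, the Youden
#' respiratory-rate threshold, the cross-validated bedside model, the
#' diagnostic-accuracy table of the two bedside predictors and the
#' multinomial three-class model.
#'
#' @param data Analysis data frame (or path to a `cohort.csv`).
#' @param out Optional path for a JSON summary of the headline numbers.
#' @param n_boot Bootstrap replicates for the AUROC CI.
#' @param seed Seed for fold assignment and the bootstrap.
#' @return A list of class `study_analysis` with the components above.
#' @export
cmd_analyze <- function(data, out = NULL, n_boot = 2000, seed = 1) {
  if (is.character(data)) data <- read_cohort_csv(data)
  d <- data[data$eligible & !is.na(data$label), , drop = FALSE]
  if (nrow(d) < 20) stop("too few eligible patients to analyze", call. = FALSE)
  d$complete <- d$label == "complete"

  absorber <- summarize_cohort(d$label, d$delta_peep_tot, d$applied_peep)
  candidates <- intersect(
    c("age", "female", "bmi", "respiratory_rate", "expiratory_time",
      "minute_ventilation", "tidal_volume_per_ibw", "resistance",
      "elastance", "flow_limited", "chronic_pulmonary_disease",
      "acute_pulmonary_disease", "smoking_history", "pao2_fio2", "supine"),
    names(d))
  screen <- univariate_screen(d, "complete", candidates)
  selected <- screen$covariate[screen$selected]
  multivar <- if (length(selected) >= 1) {
    fit_multivariable(d, "complete", selected)
  }
  thr <- choose_rr_threshold(d$respiratory_rate, d$complete)
  d$rr_below <- d$respiratory_rate < thr$threshold
  cv <- cross_validate(d, "complete", c("rr_below", "flow_limited"),
                       n_boot = n_boot, seed = seed)
  diagnostics <- list(
    flow_limited = diagnostic_metrics(d$flow_limited, d$complete),
    rr_below = diagnostic_metrics(d$rr_below, d$complete),
    both = diagnostic_metrics(d$flow_limited & d$rr_below, d$complete))
  multinomial <- fit_multinomial(d, c("rr_below", "flow_limited"))
  table1 <- characteristics_table(d, candidates)

  res <- structure(list(
    n = nrow(d), counts = absorber$counts, fractions = absorber$fractions,
    delta_hist = absorber$delta_hist, delta_pct_hist = absorber$delta_pct_hist,
    fl_prevalence = mean(d$flow_limited),
    table1 = table1, screen = screen, multivariable = multivar,
    rr_threshold = thr, cross_validation = cv, diagnostics = diagnostics,
    multinomial = multinomial
  ), class = "study_analysis")

  if (!is.null(out)) {
    headline <- list(
      n = res$n,
      complete_pct = 100 * res$fractions[["complete"]],
      high_pct = 100 * res$fractions[["high"]],
      low_pct = 100 * res$fractions[["low"]],
      fl_prevalence_pct = 100 * res$fl_prevalence,
      rr_threshold = thr$threshold,
      auroc_apparent = cv$auroc_apparent,
      auroc_corrected = cv$auroc_corrected,
      calibration_mae = cv$calibration_mae,
      fl_sensitivity = diagnostics$flow_limited$estimate[1],
      fl_specificity = diagnostics$flow_limited$estimate[2],
      fl_ppv = diagnostics$flow_limited$estimate[3],
      fl_npv = diagnostics$flow_limited$estimate[4])
    writeLines(jsonlite::toJSON(headline, auto_unbox = TRUE, pretty = TRUE,
                                digits = NA), out)
  }
  res
}

#' @export
print.study_analysis <- function(x, ...) {
  cat(sprintf("Study analysis: n = %d eligible patients\n", x$n))
  cat(sprintf("  complete / high / low: %.0f%% / %.0f%% / %.0f%%; flow limited %.0f%%\n",
              100 * x$fractions[["complete"]], 100 * x$fractions[["high"]],
              100 * x$fractions[["low"]], 100 * x$fl_prevalence))
  cat(sprintf("  RR threshold %.1f /min (Youden %.2f)\n",
              x$rr_threshold$threshold, x$rr_threshold$youden))
  cat(sprintf("  AUROC apparent %.3f, cross-validated %.3f (95%% CI %.3f-%.3f), calibration MAE %.3f\n",
              x$cross_validation$auroc_apparent,
              x$cross_validation$auroc_corrected,
              x$cross_validation$auroc_ci[1], x$cross_validation$auroc_ci[2],
              x$cross_validation$calibration_mae))
  fl <- x$diagnostics$flow_limited
  cat(sprintf("  flow limitation -> complete: Se %.2f, Sp %.2f, PPV %.2f, NPV %.2f\n",
              fl$estimate[1], fl$estimate[2], fl$estimate[3], fl$estimate[4]))
  invisible(x)
}

#' Worked example: the two-compartment reference patient
#'
#' Builds the reference patient (compartmental auto-PEEP 4 and 10 cmH2O,
#' equal compliances), runs the measurement protocol at ZEEP and after
#' applying 80 % of the measured auto-PEEP, and reports the occlusion
#' readings: total PEEP 7 at ZEEP, applied PEEP 6, total PEEP 10 on PEEP,
#' with the non-flow-limited compartment's auto-PEEP unchanged.
#'
#' @param seed Seed for the measurement noise.
#' @param quiet Suppress the narrative output.
#' @return A list with the key quantities.
#' @export
fig2_worked_example <- function(seed = 1, quiet = FALSE) {
  model <- calibrate_fig2_patient(4, 10)
  settings <- vent_settings(tidal_volume = 0.5, respiratory_rate = 15,
                            inspiratory_time = 1)
  res <- run_protocol(model, settings, protocol_config(), seed = seed)
  ss0 <- steady_state(model, set_applied_peep(settings, 0))
  ss1 <- steady_state(model, set_applied_peep(settings, res$applied_peep))
  out <- list(
    autopeep_compartments_zeep = ss0$auto_peep_compartments,
    peep_tot_zeep = res$zeep$peep_tot,
    applied_peep = res$applied_peep,
    peep_tot_on_peep = res$peep$peep_tot,
    delta_peep_tot = res$measurements$delta_peep_tot,
    delta_percent_of_applied = res$classification$delta_percent_of_applied,
    autopeep_nonfl_on_peep = ss1$palv_ee[1] - res$applied_peep,
    label = as.character(res$classification$label))
  if (!quiet) {
    cat(sprintf("Two-compartment patient: regional auto-PEEP %.2f (non-FL) and %.2f (FL) cmH2O at ZEEP\n",
                out$autopeep_compartments_zeep[1],
                out$autopeep_compartments_zeep[2]))
    cat(sprintf("Occluded total PEEP at ZEEP: %.2f cmH2O -> applied PEEP %d cmH2O (80%%, rounded)\n",
                out$peep_tot_zeep, out$applied_peep))
    cat(sprintf("Occluded total PEEP on PEEP: %.2f cmH2O (rise %.2f = %.0f%% of applied)\n",
                out$peep_tot_on_peep, out$delta_peep_tot,
                out$delta_percent_of_applied))
    cat(sprintf("Non-FL compartment auto-PEEP on PEEP: %.2f cmH2O (unchanged above the applied level)\n",
                out$autopeep_nonfl_on_peep))
  }
  invisible(out)
}

#' Validate a directory of waveform CSV exports
#'
#' Attempts to parse every `waveform*.csv` in the directory and reports,
#' per file, whether it is well formed (required columns, uniform time
#' base) and its duration.
#'
#' @param dir Directory to scan.
#' @return A data frame with `file`, `ok`, `n_samples`, `duration_s`,
#'   `message`.
#' @export
validate_waveform_dir <- function(dir) {
  files <- list.files(dir, pattern = "^waveform.*\\.csv$", full.names = TRUE)
  if (length(files) == 0) {
    stop("no waveform CSV files found in ", dir, call. = FALSE)
  }
  rows <- lapply(files, function(f) {
    ok <- TRUE; msg <- ""; ns <- NA_integer_; dur <- NA_real_
    rec <- tryCatch(read_waveform_csv(f), error = function(e) {
      ok <<- FALSE; msg <<- conditionMessage(e); NULL
    })
    if (!is.null(rec)) {
      ns <- length(rec$time)
      dur <- ns / rec$sample_rate
    }
    data.frame(file = basename(f), ok = ok, n_samples = ns, duration_s = dur,
               message = msg, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
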