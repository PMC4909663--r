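# Truncated-normal draw by rejection (bounds are always a few SDs wide here).
rtnorm <- function(n, mean, sd, lo, hi) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lo | x > hi)
  while (length(bad) > 0) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(x < lo | x > hi)
  }
  x
}

# Sub-seed for patient i so each patient's draws are reproducible and
# independent of cohort size.
sub_seed <- function(seed, i) (as.integer(seed) + 7919 * i) %% 2147483647

#' Cohort-generator configuration
#'
#' The defaults define the simulated study population: 61 % of patients are
#' expiratory flow limited (FL). FL patients are two-compartment, with a
#' dominant flow-limited region and a small fast non-FL region; the
#' "severe" FL phenotype (45 % of FL) has a very dominant FL region
#' (non-FL compliance share 2-10 %) and is ventilated at low rates, while
#' the "mixed" phenotype has a larger non-FL share (13-20 %) and ordinary
#' rates. Non-FL patients are single-compartment with a long time constant.
#' Distribution vectors are `c(mean, sd, lower, upper)` for truncated
#' normals and `c(lower, upper)` for uniforms.
#'
#' @param fl_prevalence Probability that a patient is flow limited.
#' @param severe_given_fl Probability of the severe phenotype within FL.
#' @param severe,mixed,nonfl Phenotype parameter lists (`nonfl_share`,
#'   `rr` = respiratory rate, `autopeep_fl` / `autopeep` = compartmental
#'   auto-PEEP target at ZEEP, cmH2O).
#' @param nonfl_region_autopeep Auto-PEEP range of the fast non-FL region
#'   in FL patients, cmH2O.
#' @param binding_factor Dimensionless k * (R + Raw) * C of the flow-limited
#'   compartment; 0.15 keeps the maximal-flow envelope binding throughout
#'   expiration when PEEP at 80 % of auto-PEEP is applied.
#' @param compliance Total respiratory-system compliance, L/cmH2O.
#' @param airway_resistance Airway/tube (common) resistance, cmH2O.s/L.
#' @param inspiratory_time Insufflation time range, s.
#' @param tidal_volume_per_kg Tidal volume range, mL per kg of ideal body
#'   weight.
#' @param noise_sd Pressure-sensor noise SD, cmH2O.
#' @param covariates Clinical covariate distributions; binary covariates
#'   with `_fl` / `_nonfl` suffixes are Bernoulli probabilities conditional
#'   on flow limitation.
#' @return A named list of class `cohort_config`.
#' @export
cohort_config <- function(fl_prevalence = 0.61,
                          severe_given_fl = 0.45,
                          severe = list(nonfl_share = c(0.02, 0.10),
                                        rr = c(16, 3, 10, 22),
                                        autopeep_fl = c(9.5, 2, 6.5, 14)),
                          mixed = list(nonfl_share = c(0.13, 0.20),
                                       rr = c(21, 3.5, 14, 26),
                                       autopeep_fl = c(11, 1.5, 8, 14)),
                          nonfl = list(rr = c(22, 4, 14, 30),
                                       autopeep = c(6.5, 1.5, 5.2, 11)),
                          nonfl_region_autopeep = c(0.1, 0.5),
                          binding_factor = 0.15,
                          compliance = c(0.053, 0.008, 0.035, 0.075),
                          airway_resistance = c(3, 6),
                          inspiratory_time = c(0.8, 1.1),
                          tidal_volume_per_kg = c(6, 9),
                          noise_sd = 0.2,
                          covariates = list(
                            age = c(71, 11, 30, 95),
                            female = 0.4,
                            bmi = c(27, 5, 16, 45),
                            chronic_pulmonary_fl = 0.85,
                            chronic_pulmonary_nonfl = 0.35,
                            acute_pulmonary_fl = 0.20,
                            acute_pulmonary_nonfl = 0.50,
                            smoking_fl = 0.70,
                            smoking_nonfl = 0.40,
                            pao2_fio2 = c(220, 60, 80, 400),
                            supine_fl = 0.50,
                            supine_nonfl = 0.70)) {
  structure(list(fl_prevalence = fl_prevalence,
                 severe_given_fl = severe_given_fl,
                 severe = severe, mixed = mixed, nonfl = nonfl,
                 nonfl_region_autopeep = nonfl_region_autopeep,
                 binding_factor = binding_factor,
                 compliance = compliance,
                 airway_resistance = airway_resistance,
                 inspiratory_time = inspiratory_time,
                 tidal_volume_per_kg = tidal_volume_per_kg,
                 noise_sd = noise_sd, covariates = covariates),
            class = "cohort_config")
}

check_config_fields <- function(config) {
  defaults <- cohort_config()
  bad <- setdiff(names(config), names(defaults))
  if (length(bad) > 0) {
    stop("unknown cohort_config field: ", bad[1], call. = FALSE)
  }
  for (nm in c("severe", "mixed", "nonfl", "covariates")) {
    bad <- setdiff(names(config[[nm]]), names(defaults[[nm]]))
    if (length(bad) > 0) {
      stop("unknown cohort_config field: ", nm, "$", bad[1], call. = FALSE)
    }
  }
  probs <- c(config$fl_prevalence, config$severe_given_fl)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1)) {
    stop("invalid cohort_config field: fl_prevalence and severe_given_fl ",
         "must be probabilities", call. = FALSE)
  }
  if (!is.finite(config$binding_factor) || config$binding_factor <= 0 ||
      config$binding_factor >= 1) {
    stop("invalid cohort_config field: binding_factor must lie in (0, 1)",
         call. = FALSE)
  }
  invisible(config)
}

draw_tn <- function(p) rtnorm(1, p[1], p[2], p[3], p[4])
draw_u <- function(p) stats::runif(1, p[1], p[2])

# Noiseless bedside check: does the compression maneuver superimpose with
# margin? Used by the generator so that "flow limited" patients are, by
# construction, the patients the bedside criterion identifies (the study's
# FL group is defined by this maneuver, not by hidden parameters).
fl_detectable <- function(model, settings, min_fraction = 0.25) {
  m0 <- model
  m0$noise_sd <- 0
  zeep <- set_applied_peep(settings, 0)
  ss <- steady_state(m0, zeep)
  pair <- simulate_compression(m0, zeep, ss$v_ei, delta_pressure = 10)
  det <- detect_flow_limitation(build_loop(pair$passive),
                                build_loop(pair$compressed))
  det$superimposed_fraction >= min_fraction
}

# One patient: covariates, ventilator settings and a lung model whose
# compartmental parameters are solved in closed form from the targeted
# compartmental auto-PEEPs at ZEEP.
generate_patient <- function(id, config, seed) {
  set.seed(sub_seed(seed, id))
  cv <- config$covariates
  fl <- stats::runif(1) < config$fl_prevalence
  phenotype <- if (!fl) "nonfl"
               else if (stats::runif(1) < config$severe_given_fl) "severe_fl"
               else "mixed_fl"
  ph <- switch(phenotype, severe_fl = config$severe, mixed_fl = config$mixed,
               nonfl = config$nonfl)

  age <- draw_tn(cv$age)
  female <- stats::runif(1) < cv$female
  height <- if (female) rtnorm(1, 162, 7, 145, 185) else rtnorm(1, 175, 7, 155, 200)
  ibw <- (if (female) 45.5 else 50) + 0.91 * (height - 152.4)
  bmi <- draw_tn(cv$bmi)
  chronic <- stats::runif(1) < (if (fl) cv$chronic_pulmonary_fl else cv$chronic_pulmonary_nonfl)
  acute <- stats::runif(1) < (if (fl) cv$acute_pulmonary_fl else cv$acute_pulmonary_nonfl)
  smoking <- stats::runif(1) < (if (fl) cv$smoking_fl else cv$smoking_nonfl)
  pf <- draw_tn(cv$pao2_fio2)
  supine <- stats::runif(1) < (if (fl) cv$supine_fl else cv$supine_nonfl)

  rr <- draw_tn(ph$rr)
  ti <- draw_u(config$inspiratory_time)
  vt_per_kg <- draw_u(config$tidal_volume_per_kg)
  vt <- vt_per_kg * ibw / 1000
  settings <- vent_settings(tidal_volume = vt, respiratory_rate = rr,
                            inspiratory_time = ti)
  te <- settings$expiratory_time
  ctot <- draw_tn(config$compliance)
  raw <- draw_u(config$airway_resistance)
  vte <- vt / ctot  # per-compartment tidal driving pressure (shares ~ C)

  if (fl) {
    w_n <- draw_u(ph$nonfl_share)
    w_f <- 1 - w_n
    ap_f <- draw_tn(ph$autopeep_fl)
    ap_n <- draw_u(config$nonfl_region_autopeep)
    c_n <- w_n * ctot; c_f <- w_f * ctot
    k <- log(1 + vte / ap_f) / te
    # keep the flow-limited compartment's regional resistance positive while
    # preserving the binding factor: lower the common resistance if needed
    raw <- min(raw, config$binding_factor / (k * c_f) - 0.5)
    r_f <- config$binding_factor / (k * c_f) - raw
    build <- function(ap_n) {
      tau_n <- te / log(1 + vte / ap_n)
      lung_model(list(
        lung_compartment(resistance = tau_n / c_n - raw, compliance = c_n,
                         volume_share = w_n),
        lung_compartment(resistance = r_f, compliance = c_f,
                         flow_limited = TRUE, envelope_slope = k,
                         volume_share = w_f)
      ), noise_sd = config$noise_sd, airway_resistance = raw)
    }
    model <- build(ap_n)
    # the FL phenotype is defined by the bedside maneuver: when a short
    # expiration leaves the non-FL region dribbling above the detector
    # tolerance, speed that region up (halve its trapped pressure) until
    # the loops superimpose with margin
    for (try in 1:6) {
      if (fl_detectable(model, settings)) break
      ap_n <- ap_n / 2
      model <- build(ap_n)
    }
    ap_true <- w_n * ap_n + w_f * ap_f
  } else {
    w_n <- 1; ap_f <- NA_real_
    ap_n <- draw_tn(ph$autopeep)
    tau <- te / log(1 + vte / ap_n)
    model <- lung_model(list(
      lung_compartment(resistance = tau / ctot - raw, compliance = ctot)
    ), noise_sd = config$noise_sd, airway_resistance = raw)
    ap_true <- ap_n
  }

  list(row = data.frame(
         id = id, phenotype = phenotype, flow_limited_true = fl,
         age = age, female = female, height = height, ibw = ibw, bmi = bmi,
         chronic_pulmonary_disease = chronic, acute_pulmonary_disease = acute,
         smoking_history = smoking, pao2_fio2 = pf, supine = supine,
         respiratory_rate = rr, inspiratory_time = ti,
         tidal_volume = vt, tidal_volume_per_ibw = vt_per_kg,
         expiratory_time = te,
         minute_ventilation = settings$minute_ventilation,
         compliance_true = ctot, airway_resistance = raw,
         nonfl_share = w_n, autopeep_fl_true = ap_f,
         autopeep_nonfl_true = ap_n, autopeep_true = ap_true,
         stringsAsFactors = FALSE),
       model = model, settings = settings)
}

#' Generate a simulated patient cohort
#'
#' Draws `n` patients from [cohort_config()]: clinical covariates,
#' ventilator settings and a per-patient [lung_model()]. Each patient uses
#' an independent sub-seed derived from `seed`, so patient `i` is identical
#' across cohort sizes.
#'
#' @param n Number of patients.
#' @param config A [cohort_config()].
#' @param seed Integer seed.
#' @return An object of class `cohort`: `patients` (data frame of
#'   covariates, settings and true parameters), `models`, `settings`
#'   (per-patient lists), `config` and `seed`.
#' @export
generate_cohort <- function(n, config = cohort_config(), seed = 1) {
  stopifnot(is.numeric(n), length(n) == 1, n >= 1)
  check_config_fields(config)
  pts <- lapply(seq_len(n), generate_patient, config = config, seed = seed)
  structure(list(
    patients = do.call(rbind, lapply(pts, `[[`, "row")),
    models = lapply(pts, `[[`, "model"),
    settings = lapply(pts, `[[`, "settings"),
    config = config, seed = seed
  ), class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("Simulated cohort: %d patients (seed %d), %.0f%% flow limited (true)\n",
              nrow(x$patients), x$seed, 100 * mean(x$patients$flow_limited_true)))
  invisible(x)
}

#' Run the measurement protocol on every patient of a cohort
#'
#' Applies [run_protocol()] patient by patient (per-patient sub-seeds
#' derived from `seed`) and assembles the analysis dataset: measured
#' mechanics at ZEEP, the bedside flow-limitation verdict, the applied
#' PEEP, the change in total PEEP and the absorber label, joined to the
#' generated covariates.
#'
#' @param cohort A [generate_cohort()] result.
#' @param config A [protocol_config()].
#' @param seed Integer seed for the measurement noise.
#' @param keep_results Keep the per-patient `protocol_result` objects.
#' @return An object of class `study_result` with `data` (one row per
#'   patient; ineligible patients have `eligible = FALSE` and `NA`
#'   outcomes) and optionally `results`.
#' @export
run_study <- function(cohort, config = protocol_config(), seed = 1,
                      keep_results = FALSE) {
  stopifnot(inherits(cohort, "cohort"))
  n <- nrow(cohort$patients)
  rows <- vector("list", n)
  results <- if (keep_results) vector("list", n)
  for (i in seq_len(n)) {
    res <- run_protocol(cohort$models[[i]], cohort$settings[[i]], config,
                        seed = sub_seed(seed, i))
    el <- res$eligible
    rows[[i]] <- data.frame(
      id = cohort$patients$id[i],
      eligible = el,
      valid = res$valid,
      flow_limited = res$flow_limited,
      auto_peep = res$auto_peep_zeep,
      resistance = res$zeep$resistance,
      elastance = res$zeep$elastance,
      compliance = res$zeep$compliance,
      applied_peep = if (el) res$applied_peep else NA_real_,
      peep_tot_zeep = res$zeep$peep_tot,
      peep_tot_peep = if (el) res$peep$peep_tot else NA_real_,
      delta_peep_tot = if (el) res$measurements$delta_peep_tot else NA_real_,
      delta_percent_of_applied =
        if (el) res$classification$delta_percent_of_applied else NA_real_,
      label = if (el) as.character(res$classification$label) else NA_character_,
      stringsAsFactors = FALSE)
    if (keep_results) results[[i]] <- res
  }
  meas <- do.call(rbind, rows)
  data <- merge(cohort$patients, meas, by = "id", sort = TRUE)
  data$label <- factor(data$label, levels = c("complete", "high", "low"))
  structure(list(data = data, results = results, seed = seed,
                 protocol = config),
            class = "study_result")
}

#' @export
print.study_result <- function(x, ...) {
  d <- x$data
  el <- d[d$eligible, , drop = FALSE]
  cat(sprintf("Study: %d patients, %d eligible; FL %.0f%%\n",
              nrow(d), nrow(el), 100 * mean(el$flow_limited)))
  print(round(100 * prop.table(table(el$label)), 1))
  invisible(x)
}
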