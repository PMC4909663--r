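#' Single lung compartment with optional expiratory flow limitation
#'
#' A compartment is a linear RC unit (regional resistance and compliance).
#' A flow-limited compartment additionally carries a maximal-expiratory-flow
#' envelope, Vdot_max(V) = k * V, where V is the compartment volume above its
#' relaxation volume: whenever the Ohmic (pressure-driven) flow exceeds k*V,
#' expiratory flow is clipped to the envelope and becomes independent of the
#' downstream (airway-opening) pressure. This is the minimal one-parameter
#' representation of wave-speed / Starling-resistor behaviour.
#'
#' @param resistance Regional resistance in cmH2O.s/L (> 0).
#' @param compliance Regional compliance in L/cmH2O (> 0).
#' @param flow_limited Logical; does the maximal-flow envelope apply?
#' @param envelope_slope Envelope slope k in (L/s)/L; required (and > 0) when
#'   `flow_limited`, must be absent otherwise.
#' @param volume_share Fraction of each tidal breath delivered to this
#'   compartment (shares across a model must sum to 1).
#' @return An object of class `lung_compartment`.
#' @examples
#' lung_compartment(20, 0.05)
#' lung_compartment(15, 0.025, flow_limited = TRUE, envelope_slope = 0.25,
#'                  volume_share = 0.5)
#' @export
lung_compartment <- function(resistance, compliance, flow_limited = FALSE,
                             envelope_slope = NULL, volume_share = 1) {
  if (resistance <= 0) stop("resistance must be > 0", call. = FALSE)
  if (compliance <= 0) stop("compliance must be > 0", call. = FALSE)
  if (volume_share <= 0 || volume_share > 1) {
    stop("volume_share must be in (0, 1]", call. = FALSE)
  }
  if (flow_limited) {
    if (is.null(envelope_slope) || envelope_slope <= 0) {
      stop("a flow-limited compartment needs envelope_slope > 0", call. = FALSE)
    }
  } else if (!is.null(envelope_slope)) {
    stop("envelope_slope must be absent unless flow_limited", call. = FALSE)
  }
  structure(list(resistance = resistance, compliance = compliance,
                 flow_limited = flow_limited,
                 envelope_slope = if (flow_limited) envelope_slope else NA_real_,
                 volume_share = volume_share),
            class = "lung_compartment")
}

#' Compartmental lung model
#'
#' Ground truth for the simulator: one or more parallel RC compartments, an
#' optional common airway resistance (endotracheal tube plus central airways,
#' contributing to the resistive pressure drop but shared by all
#' compartments), and a pressure-sensor noise level.
#'
#' @param compartments A `lung_compartment` or list of them (volume shares
#'   must sum to 1).
#' @param noise_sd Gaussian pressure-sensor noise SD in cmH2O (default 0.2).
#' @param airway_resistance Common series resistance in cmH2O.s/L (>= 0).
#' @return An object of class `lung_model`.
#' @examples
#' lung_model(lung_compartment(20, 0.05), noise_sd = 0)
#' @export
lung_model <- function(compartments, noise_sd = 0.2, airway_resistance = 0) {
  if (inherits(compartments, "lung_compartment")) compartments <- list(compartments)
  if (length(compartments) < 1) stop("at least one compartment", call. = FALSE)
  if (!all(vapply(compartments, inherits, TRUE, "lung_compartment"))) {
    stop("compartments must be lung_compartment objects", call. = FALSE)
  }
  shares <- vapply(compartments, `[[`, 1, "volume_share")
  if (abs(sum(shares) - 1) > 1e-8) {
    stop("volume_share values must sum to 1 (got ", signif(sum(shares), 4), ")",
         call. = FALSE)
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (airway_resistance < 0) stop("airway_resistance must be >= 0", call. = FALSE)
  structure(list(compartments = compartments, noise_sd = noise_sd,
                 airway_resistance = airway_resistance),
            class = "lung_model")
}

#' @export
print.lung_model <- function(x, ...) {
  p <- model_pars(x)
  cat(sprintf("Lung model: %d compartment(s), Raw %.1f, noise SD %.2f cmH2O\n",
              length(x$compartments), x$airway_resistance, x$noise_sd))
  for (i in seq_along(p$C)) {
    cat(sprintf("  #%d share %.2f  R %.1f cmH2O.s/L  C %.4f L/cmH2O%s\n",
                i, p$w[i], p$R[i], p$C[i],
                if (p$fl[i]) sprintf("  FL envelope k %.3f /s", p$k[i]) else ""))
  }
  invisible(x)
}

# Flat parameter vectors for internal numerics.
model_pars <- function(model) {
  comps <- model$compartments
  list(
    R = vapply(comps, `[[`, 1, "resistance"),
    C = vapply(comps, `[[`, 1, "compliance"),
    k = vapply(comps, `[[`, 1, "envelope_slope"),
    fl = vapply(comps, `[[`, TRUE, "flow_limited"),
    w = vapply(comps, `[[`, 1, "volume_share"),
    Raw = model$airway_resistance
  )
}

# Closed-form expiration of one compartment.
#
# State variable: volume V above the relaxation volume at zero alveolar
# pressure, so alveolar pressure is V / C. Ohmic emptying follows
# dV/dt = -(V/C + delta - p0) / (R + Raw); a flow-limited compartment is
# clipped to the envelope k * V wherever that is smaller. `delta` is an
# external (abdominal compression) pressure added to the alveolar pressure
# for the whole expiration. Volume is floored at 0 (airway closure at the
# relaxation volume). Returns volumes and expiratory flows at times `t`
# (seconds from the start of expiration).
expire_compartment <- function(v0, C, Reff, k, p0, delta, t) {
  tau <- Reff * C
  veq <- C * (p0 - delta)
  ohmic <- function(vstart, tt) {
    v <- veq + (vstart - veq) * exp(-tt / tau)
    if (veq < 0) {
      tf <- tau * log((vstart - veq) / (-veq))
      v[tt >= tf] <- 0
    }
    v
  }
  if (is.na(k)) {
    v <- ohmic(v0, t)
    return(list(v = v, flow = (v - veq) / tau * (v > 0 | veq >= 0)))
  }
  if (k >= 1 / tau) {
    # Envelope slack everywhere the compartment still holds gas above the
    # ohmic equilibrium: fall back to fine-grained stepping.
    return(expire_stepped(v0, C, Reff, k, p0, delta, t))
  }
  vs <- C * (p0 - delta) / (1 - k * tau)   # envelope binds for V >= vs
  n <- length(t)
  v <- numeric(n); flow <- numeric(n)
  if (v0 >= vs) {
    tsw <- if (vs <= 0) Inf else log(v0 / vs) / k
    on_env <- t <= tsw
    v[on_env] <- v0 * exp(-k * t[on_env])
    flow[on_env] <- k * v[on_env]
    if (any(!on_env)) {
      idx <- which(!on_env)
      v2 <- ohmic(vs, t[idx] - tsw)
      v[idx] <- v2
      flow[idx] <- (v2 - veq) / tau
      flow[idx[v2 <= 0 & veq < 0]] <- 0
    }
  } else {
    v <- ohmic(v0, t)
    flow <- (v - veq) / tau
    flow[v <= 0 & veq < 0] <- 0
  }
  list(v = v, flow = flow)
}

# Per-sample fallback for envelope slopes that are not everywhere below the
# Ohmic rate; exact within each sub-step regime.
expire_stepped <- function(v0, C, Reff, k, p0, delta, t, dt = 0.002) {
  tau <- Reff * C
  veq <- C * (p0 - delta)
  tmax <- max(t)
  nt <- ceiling(tmax / dt)
  tt <- seq(0, by = dt, length.out = nt + 1)
  vv <- numeric(nt + 1)
  vv[1] <- v0
  v <- v0
  for (i in seq_len(nt)) {
    f_ohm <- (v - veq) / tau
    if (!is.na(k) && k * v < f_ohm) {
      v <- v * exp(-k * dt)
    } else {
      v <- veq + (v - veq) * exp(-dt / tau)
      if (v < 0) v <- 0
    }
    vv[i + 1] <- v
  }
  v_at <- stats::approx(tt, vv, xout = t, rule = 2)$y
  f_ohm <- (v_at - veq) / tau
  f_env <- if (is.na(k)) Inf else k * v_at
  flow <- pmin(f_ohm, f_env)
  flow[v_at <= 0 & flow < 0 & veq < 0] <- 0
  list(v = v_at, flow = flow)
}

# Advance compartment volumes across one breath (valve semantics: no
# expiratory flow during insufflation, so inspiration adds w_i * VT; then a
# closed-form passive expiration over Te). Returns end-expiratory volumes.
advance_breath <- function(v_ee, pars, settings, delta = 0) {
  v_ei <- v_ee + pars$w * settings$tidal_volume
  p0 <- settings$applied_peep
  vapply(seq_along(v_ei), function(i) {
    expire_compartment(v_ei[i], pars$C[i], pars$R[i] + pars$Raw, pars$k[i],
                       p0, delta, settings$expiratory_time)$v
  }, 0)
}

#' Steady-state breathing pattern of a lung model
#'
#' Iterates whole breaths (constant-flow insufflation followed by passive
#' expiration) from the relaxed state until the end-expiratory volumes reach
#' a fixed point. Dynamic hyperinflation, if any, is the end-expiratory
#' volume retained above the equilibrium volume at the applied PEEP.
#'
#' @param model A [lung_model()].
#' @param settings A [vent_settings()].
#' @param tol Convergence tolerance on end-expiratory volume (L).
#' @param max_breaths Iteration cap.
#' @return A list with per-compartment end-expiratory and end-inspiratory
#'   volumes (`v_ee`, `v_ei`, L above relaxation volume) and alveolar
#'   pressures (`palv_ee`, `palv_ei`, cmH2O), plus `auto_peep` and
#'   `peep_tot`: the compliance-weighted end-expiratory alveolar pressure
#'   above / including applied PEEP (what an end-expiratory occlusion
#'   plateau reads).
#' @export
steady_state <- function(model, settings, tol = 1e-9, max_breaths = 2000) {
  pars <- model_pars(model)
  v <- pars$C * settings$applied_peep   # relaxed at applied PEEP
  for (i in seq_len(max_breaths)) {
    v_new <- advance_breath(v, pars, settings)
    if (max(abs(v_new - v)) < tol) { v <- v_new; break }
    v <- v_new
  }
  state_from_volumes(v, pars, settings)
}

state_from_volumes <- function(v_ee, pars, settings) {
  v_ei <- v_ee + pars$w * settings$tidal_volume
  palv_ee <- v_ee / pars$C
  palv_ei <- v_ei / pars$C
  pstar_ee <- sum(pars$C * palv_ee) / sum(pars$C)
  pstar_ei <- sum(pars$C * palv_ei) / sum(pars$C)
  list(v_ee = v_ee, v_ei = v_ei, palv_ee = palv_ee, palv_ei = palv_ei,
       pstar_ee = pstar_ee, pstar_ei = pstar_ei,
       peep_tot = pstar_ee,
       auto_peep = pstar_ee - settings$applied_peep,
       auto_peep_compartments = palv_ee - settings$applied_peep)
}

#' Calibrate the two-compartment explanatory model
#'
#' Builds a lung with a non-flow-limited and a flow-limited region of equal
#' volume share whose steady-state compartmental auto-PEEPs at ZEEP hit the
#' requested targets: root-finding over the regional resistance for the
#' non-FL region and over the envelope slope for the FL region. With the
#' default targets (4 and 10 cmH2O) the occluded total PEEP at ZEEP is their
#' compliance-weighted mean, 7 cmH2O.
#'
#' @param target_autopeep_nfl Target auto-PEEP of the non-flow-limited
#'   region at ZEEP (cmH2O, > 0).
#' @param target_autopeep_fl Target auto-PEEP of the flow-limited region at
#'   ZEEP (cmH2O, > 0).
#' @param settings Ventilator prescription; defaults to VT 0.5 L, RR 15/min,
#'   Ti 1 s at ZEEP.
#' @param compliance Total respiratory-system compliance in L/cmH2O (split
#'   evenly between the regions).
#' @param fl_resistance Regional resistance of the FL region (its emptying is
#'   governed by the envelope, so this only sets the Ohmic ceiling).
#' @param noise_sd Sensor noise handed to the resulting [lung_model()].
#' @param tol Calibration tolerance in cmH2O.
#' @return A two-compartment `lung_model`.
#' @examples
#' m <- calibrate_fig2_patient(4, 10)
#' steady_state(m, vent_settings(0.5, 15, 1))$peep_tot  # 7 cmH2O
#' @export
calibrate_fig2_patient <- function(target_autopeep_nfl, target_autopeep_fl,
                                   settings = vent_settings(0.5, 15, 1),
                                   compliance = 0.05, fl_resistance = 20,
                                   noise_sd = 0.2, tol = 0.05) {
  stopifnot(target_autopeep_nfl > 0, target_autopeep_fl > 0)
  zeep <- set_applied_peep(settings, 0)
  Ci <- compliance / 2

  ap_of <- function(model) steady_state(model, zeep)$auto_peep_compartments

  # Non-FL region: auto-PEEP is monotone increasing in R.
  nfl_model <- function(R) lung_model(list(
    lung_compartment(R, Ci, volume_share = 0.5),
    lung_compartment(R, Ci, volume_share = 0.5)), noise_sd = 0)
  f_nfl <- function(R) ap_of(nfl_model(R))[1] - target_autopeep_nfl
  lo <- 0.5; hi <- 2000
  if (f_nfl(hi) < 0 || f_nfl(lo) > 0) {
    stop("calibration failure: non-FL auto-PEEP target ", target_autopeep_nfl,
         " unreachable; residual at bounds ", signif(f_nfl(lo), 3), " / ",
         signif(f_nfl(hi), 3), call. = FALSE)
  }
  R_nfl <- stats::uniroot(f_nfl, c(lo, hi), tol = 1e-7)$root

  # FL region: auto-PEEP is monotone decreasing in the envelope slope k.
  k_hi <- 0.98 / ((fl_resistance + 0) * Ci)   # keep envelope below Ohmic rate
  fl_model <- function(k) lung_model(list(
    lung_compartment(R_nfl, Ci, volume_share = 0.5),
    lung_compartment(fl_resistance, Ci, flow_limited = TRUE,
                     envelope_slope = k, volume_share = 0.5)), noise_sd = 0)
  f_fl <- function(k) ap_of(fl_model(k))[2] - target_autopeep_fl
  if (f_fl(1e-4) < 0 || f_fl(k_hi) > 0) {
    stop("calibration failure: FL auto-PEEP target ", target_autopeep_fl,
         " unreachable; residual at bounds ", signif(f_fl(1e-4), 3), " / ",
         signif(f_fl(k_hi), 3), call. = FALSE)
  }
  k_fl <- stats::uniroot(f_fl, c(1e-4, k_hi), tol = 1e-8)$root

  model <- lung_model(list(
    lung_compartment(R_nfl, Ci, volume_share = 0.5),
    lung_compartment(fl_resistance, Ci, flow_limited = TRUE,
                     envelope_slope = k_fl, volume_share = 0.5)),
    noise_sd = noise_sd)
  got <- ap_of(model)
  resid <- c(got[1] - target_autopeep_nfl, got[2] - target_autopeep_fl)
  if (max(abs(resid)) > max(tol, 0.1)) {
    stop("calibration failure: residuals ", paste(signif(resid, 3), collapse = ", "),
         " cmH2O", call. = FALSE)
  }
  model
}
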