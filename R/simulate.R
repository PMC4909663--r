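#' @title Waveform recordings
#' @description A `waveform_recording` holds uniformly sampled airway
#' pressure (cmH2O), airway-opening flow (L/s, inspiratory positive) and
#' integrated volume (L, zeroed at each breath's start of inspiration),
#' together with per-sample phase labels
#' (`insp`, `exp`, `occl_insp`, `occl_exp`, `compression`) and labelled
#' annotation intervals.
#' @name waveform_recording
NULL

new_recording <- function(time, paw, flow, volume, phase, sample_rate,
                          annotations = NULL) {
  if (is.null(annotations)) {
    annotations <- data.frame(start = numeric(0), end = numeric(0),
                              label = character(0))
  }
  structure(list(time = time, paw = paw, flow = flow, volume = volume,
                 phase = phase, sample_rate = sample_rate,
                 annotations = annotations),
            class = "waveform_recording")
}

#' @export
print.waveform_recording <- function(x, ...) {
  cat(sprintf("Waveform recording: %d samples at %g Hz (%.2f s), phases: %s\n",
              length(x$time), x$sample_rate, length(x$time) / x$sample_rate,
              paste(unique(x$phase), collapse = ", ")))
  invisible(x)
}

#' @export
as.data.frame.waveform_recording <- function(x, ...) {
  data.frame(time_s = x$time, paw_cmh2o = x$paw, flow_lps = x$flow,
             volume_l = x$volume, phase = x$phase)
}

check_step_size <- function(pars, sample_rate) {
  tau_min <- min((pars$R + pars$Raw) * pars$C)
  if (1 / sample_rate > tau_min / 2) {
    stop("step-size error: sampling interval ", signif(1 / sample_rate, 3),
         " s cannot resolve the smallest compartmental time constant ",
         signif(tau_min, 3), " s; raise sample_rate",
         call. = FALSE)
  }
}

# Airway pressure during constant-flow insufflation: common resistive drop
# plus the compliance-weighted mean of the regional (alveolar + regional
# resistive) pressures, with flow split by volume share.
insp_pressure <- function(v, pars, flow_total) {
  wC <- pars$C / sum(pars$C)
  flow_total * pars$Raw +
    sum(wC * (v / pars$C + pars$w * flow_total * pars$R))
}

render_breath <- function(v_start, pars, settings, sample_rate, delta = 0,
                          phase_exp = "exp") {
  dt <- 1 / sample_rate
  n_i <- max(1L, round(settings$inspiratory_time * sample_rate))
  n_e <- max(1L, round(settings$expiratory_time * sample_rate))
  q <- settings$inspiratory_flow
  t_i <- dt * seq_len(n_i)
  wC <- pars$C / sum(pars$C)
  # inspiration: each compartment fills at share * q
  elastic <- sapply(seq_along(pars$C), function(i) {
    (v_start[i] + pars$w[i] * q * t_i) / pars$C[i]
  })
  if (is.null(dim(elastic))) elastic <- matrix(elastic, nrow = 1)
  paw_i <- q * (pars$Raw + sum(wC * pars$w * pars$R)) +
    as.vector(elastic %*% wC)
  v_ei <- v_start + pars$w * settings$tidal_volume
  # expiration
  t_e <- dt * seq_len(n_e)
  p0 <- settings$applied_peep
  vmat <- matrix(0, n_e, length(pars$C))
  fmat <- matrix(0, n_e, length(pars$C))
  for (i in seq_along(pars$C)) {
    ex <- expire_compartment(v_ei[i], pars$C[i], pars$R[i] + pars$Raw,
                             pars$k[i], p0, delta, t_e)
    vmat[, i] <- ex$v
    fmat[, i] <- ex$flow
  }
  flow_e <- -rowSums(fmat)
  paw_e <- rep(p0, n_e)
  flow <- c(rep(q, n_i), flow_e)
  paw <- c(paw_i, paw_e)
  volume <- cumsum(flow) * dt
  list(time = dt * seq_len(n_i + n_e), paw = paw, flow = flow,
       volume = volume,
       phase = c(rep("insp", n_i), rep(phase_exp, n_e)),
       v_end = vmat[n_e, ], v_ei = v_ei)
}

#' Simulate passive volume-controlled breaths
#'
#' Renders `n_breaths` constant-flow breaths of the given model and
#' prescription. Inspiratory flow is split across compartments by volume
#' share; expiration is passive, with flow-limited compartments clipped to
#' their maximal-flow envelope (on the envelope, flow is independent of the
#' applied PEEP). Integration uses exact piecewise-exponential updates, so
#' it is unconditionally stable; a step-size error is raised only when the
#' sampling interval is too coarse to resolve the fastest compartment.
#'
#' @param model A [lung_model()].
#' @param settings A [vent_settings()].
#' @param n_breaths Number of breaths (>= 1).
#' @param sample_rate Sampling rate in Hz.
#' @param seed Optional integer seed for the sensor-noise draws.
#' @param state Optional starting end-expiratory compartment volumes (L); by
#'   default breathing starts from the relaxed state at the applied PEEP, so
#'   enough breaths must be simulated to reach steady state (or pass
#'   `steady_state(model, settings)$v_ee`).
#' @return A [waveform_recording] with breath-boundary annotations.
#' @examples
#' m <- lung_model(lung_compartment(20, 0.05), noise_sd = 0)
#' s <- vent_settings(0.5, 20, 1)
#' rec <- simulate_breaths(m, s, n_breaths = 3,
#'                         state = steady_state(m, s)$v_ee)
#' @export
simulate_breaths <- function(model, settings, n_breaths, sample_rate = 100,
                             seed = NULL, state = NULL) {
  stopifnot(inherits(model, "lung_model"), inherits(settings, "vent_settings"),
            n_breaths >= 1)
  pars <- model_pars(model)
  check_step_size(pars, sample_rate)
  if (!is.null(seed)) set.seed(as.integer(seed))
  v <- if (is.null(state)) pars$C * settings$applied_peep else state
  out <- vector("list", n_breaths)
  t0 <- 0
  ann <- data.frame(start = numeric(0), end = numeric(0), label = character(0))
  for (b in seq_len(n_breaths)) {
    br <- render_breath(v, pars, settings, sample_rate)
    out[[b]] <- data.frame(time = t0 + br$time, paw = br$paw, flow = br$flow,
                           volume = br$volume, phase = br$phase)
    ann <- rbind(ann, data.frame(start = t0, end = t0 + max(br$time),
                                 label = sprintf("breath_%d", b)))
    t0 <- t0 + max(br$time)
    v <- br$v_end
  }
  d <- do.call(rbind, out)
  noise <- if (model$noise_sd > 0) stats::rnorm(nrow(d), 0, model$noise_sd) else 0
  rec <- new_recording(d$time, d$paw + noise, d$flow, d$volume, d$phase,
                       sample_rate, ann)
  attr(rec, "v_end") <- v
  rec
}

#' Simulate an airway occlusion maneuver
#'
#' Clamps airway-opening flow to zero from the given state (end-inspiratory
#' or end-expiratory). With several compartments, gas redistributes through
#' the regional resistances via the shared airway (pendelluft), so the
#' occluded airway pressure converges to the compliance-weighted mean
#' alveolar pressure P* = sum(C_i P_i) / sum(C_i). The solution of the
#' linear redistribution system is evaluated in closed form.
#'
#' @param model A [lung_model()].
#' @param settings A [vent_settings()] (used for the applied-PEEP reference
#'   of the pre-occlusion state when `state` is omitted).
#' @param state Compartment volumes (L) at the start of the occlusion;
#'   typically `steady_state(...)$v_ei` or `$v_ee`.
#' @param kind `"end_inspiratory"` or `"end_expiratory"` (label only; the
#'   physics is set by `state`).
#' @param duration Occlusion length in seconds (study protocol: 4 s).
#' @param sample_rate Sampling rate in Hz.
#' @param seed Optional seed for sensor noise.
#' @param conductance Inter-compartment equilibration conductance in
#'   L/(s.cmH2O); the default reaches the plateau well within a 4-s
#'   occlusion for typical compartments.
#' @return A [waveform_recording] segment with phase `occl_insp` or
#'   `occl_exp`; if the plateau criterion (|dP/dt| < 0.05 cmH2O/s) is not
#'   met before `duration`, a `plateau_not_reached` annotation is added and
#'   a warning raised.
#' @export
simulate_occlusion <- function(model, settings, state,
                               kind = c("end_inspiratory", "end_expiratory"),
                               duration = 4, sample_rate = 100, seed = NULL,
                               conductance = 0.05) {
  kind <- match.arg(kind)
  stopifnot(duration > 0)
  pars <- model_pars(model)
  if (!is.null(seed)) set.seed(as.integer(seed))
  p_init <- state / pars$C
  nC <- length(pars$C)
  dt <- 1 / sample_rate
  tt <- dt * seq_len(round(duration * sample_rate))
  if (nC == 1) {
    p <- matrix(p_init, length(tt), 1)
  } else {
    # Each compartment exchanges gas with a common node through a fixed
    # conductance; the compliance-weighted mean pressure is conserved, so
    # the plateau is exactly P*.
    g <- rep(conductance, nC)
    S <- sum(g)
    A <- diag(-g / pars$C) + (g / pars$C) %o% (g / S)
    eg <- eigen(A)
    coef <- solve(eg$vectors, p_init)
    modes <- eg$vectors * matrix(coef, nC, nC, byrow = TRUE)  # V diag(coef)
    p <- Re(exp(outer(tt, eg$values)) %*% t(modes))
  }
  g <- 1 / pars$R
  paw <- as.vector(p %*% (g / sum(g)))
  # plateau slope over the final 0.5 s
  n_win <- max(2L, round(0.5 * sample_rate))
  tail_idx <- (length(paw) - n_win + 1):length(paw)
  slope <- stats::coef(stats::lm(paw[tail_idx] ~ tt[tail_idx]))[2]
  phase <- if (kind == "end_inspiratory") "occl_insp" else "occl_exp"
  ann <- data.frame(start = 0, end = duration, label = phase)
  if (abs(slope) > 0.05) {
    warning("occlusion plateau not reached within ", duration, " s (|dP/dt| = ",
            signif(abs(slope), 2), " cmH2O/s)", call. = FALSE)
    ann <- rbind(ann, data.frame(start = 0, end = duration,
                                 label = "plateau_not_reached"))
  }
  noise <- if (model$noise_sd > 0) stats::rnorm(length(paw), 0, model$noise_sd) else 0
  new_recording(tt, paw + noise, rep(0, length(tt)), rep(0, length(tt)),
                rep(phase, length(tt)), sample_rate, ann)
}

#' Simulate paired passive and abdominal-compression expirations
#'
#' From end-inspiration, renders one passive expiration and one during which
#' a constant external pressure `delta_pressure` is added to every
#' compartment's alveolar pressure for the whole expiration (firm manual
#' compression of the abdomen, applied as soon as insufflation ends and
#' maintained throughout). Non-flow-limited compartments empty faster;
#' flow-limited compartments stay clipped to their envelope, so their
#' flow-volume trajectory is unchanged wherever the envelope binds.
#'
#' @inheritParams simulate_occlusion
#' @param delta_pressure Compression pressure in cmH2O (> 0; default 10).
#' @return A list with `passive` and `compressed` [waveform_recording]
#'   expiration segments.
#' @export
simulate_compression <- function(model, settings, state, delta_pressure = 10,
                                 sample_rate = 100, seed = NULL) {
  stopifnot(delta_pressure > 0)
  pars <- model_pars(model)
  check_step_size(pars, sample_rate)
  if (!is.null(seed)) set.seed(as.integer(seed))
  render_exp <- function(delta, phase) {
    dt <- 1 / sample_rate
    t_e <- dt * seq_len(max(1L, round(settings$expiratory_time * sample_rate)))
    fmat <- sapply(seq_along(pars$C), function(i) {
      expire_compartment(state[i], pars$C[i], pars$R[i] + pars$Raw,
                         pars$k[i], settings$applied_peep, delta, t_e)$flow
    })
    if (is.null(dim(fmat))) fmat <- matrix(fmat, nrow = length(t_e))
    flow <- -rowSums(fmat)
    paw <- rep(settings$applied_peep, length(t_e)) +
      if (model$noise_sd > 0) stats::rnorm(length(t_e), 0, model$noise_sd) else 0
    new_recording(t_e, paw, flow, cumsum(flow) * dt,
                  rep(phase, length(t_e)), sample_rate,
                  data.frame(start = 0, end = max(t_e), label = phase))
  }
  list(passive = render_exp(0, "exp"),
       compressed = render_exp(delta_pressure, "compression"))
}
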