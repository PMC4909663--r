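#' Ventilator prescription for passive volume-controlled ventilation
#'
#' Bundles the controlled-ventilation settings used throughout the package:
#' constant-flow volume-controlled breaths defined by tidal volume,
#' respiratory rate, inspiratory time and applied PEEP. Inspiratory flow is
#' derived as `tidal_volume / inspiratory_time`; expiratory time as
#' `60 / respiratory_rate - inspiratory_time`.
#'
#' @param tidal_volume Tidal volume in L (> 0).
#' @param respiratory_rate Breaths per minute (> 0).
#' @param inspiratory_time Inspiratory time in seconds (> 0).
#' @param applied_peep Applied (external) PEEP in cmH2O (>= 0).
#'
#' @return An object of class `vent_settings`: a list with the four inputs
#'   plus `inspiratory_flow` (L/s), `expiratory_time` (s) and
#'   `minute_ventilation` (L/min).
#' @examples
#' vent_settings(0.5, 15, 1)
#' @export
vent_settings <- function(tidal_volume, respiratory_rate, inspiratory_time,
                          applied_peep = 0) {
  stopifnot(is.numeric(tidal_volume), is.numeric(respiratory_rate),
            is.numeric(inspiratory_time), is.numeric(applied_peep))
  if (tidal_volume <= 0) stop("tidal_volume must be > 0", call. = FALSE)
  if (respiratory_rate <= 0) stop("respiratory_rate must be > 0", call. = FALSE)
  if (inspiratory_time <= 0) stop("inspiratory_time must be > 0", call. = FALSE)
  if (applied_peep < 0) stop("applied_peep must be >= 0", call. = FALSE)
  te <- 60 / respiratory_rate - inspiratory_time
  if (te <= 0) {
    stop("invalid settings: expiratory time 60/RR - Ti = ",
         signif(te, 3), " s must be > 0", call. = FALSE)
  }
  structure(list(
    tidal_volume = tidal_volume,
    respiratory_rate = respiratory_rate,
    inspiratory_time = inspiratory_time,
    applied_peep = applied_peep,
    inspiratory_flow = tidal_volume / inspiratory_time,
    expiratory_time = te,
    minute_ventilation = tidal_volume * respiratory_rate
  ), class = "vent_settings")
}

#' @export
print.vent_settings <- function(x, ...) {
  cat("Ventilator settings (volume-controlled, constant flow)\n")
  cat(sprintf("  VT %.3f L, RR %.1f /min, Ti %.2f s (Te %.2f s), PEEP %.1f cmH2O\n",
              x$tidal_volume, x$respiratory_rate, x$inspiratory_time,
              x$expiratory_time, x$applied_peep))
  cat(sprintf("  inspiratory flow %.3f L/s, minute ventilation %.1f L/min\n",
              x$inspiratory_flow, x$minute_ventilation))
  invisible(x)
}

#' Modify the applied PEEP of a ventilator prescription
#'
#' All other settings are kept, mirroring the study protocol in which PEEP is
#' titrated while ventilation is otherwise unchanged.
#'
#' @param settings A [vent_settings()] object.
#' @param applied_peep New applied PEEP in cmH2O.
#' @return A new `vent_settings` object.
#' @export
set_applied_peep <- function(settings, applied_peep) {
  stopifnot(inherits(settings, "vent_settings"))
  vent_settings(settings$tidal_volume, settings$respiratory_rate,
                settings$inspiratory_time, applied_peep)
}
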