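#' Build an expiratory flow-volume loop from an expiration segment
#'
#' Resamples the expiratory flow magnitude onto a uniform expired-volume
#' grid, the representation in which passive and abdominal-compression
#' expirations are superimposed at the bedside.
#'
#' @param segment A [waveform_recording] covering one complete expiration
#'   (phase `exp` or `compression`).
#' @param n_grid Number of grid points (default 200).
#' @param maneuver_id Optional repetition label (1-3).
#' @return An object of class `flow_volume_loop` with `expired_volume` (L),
#'   `expiratory_flow` (L/s, magnitude) and `maneuver_id`.
#' @export
build_loop <- function(segment, n_grid = 200, maneuver_id = NA_integer_) {
  stopifnot(inherits(segment, "waveform_recording"))
  keep <- segment$phase %in% c("exp", "compression")
  if (!any(keep)) stop("segment contains no expiratory samples", call. = FALSE)
  flow <- -segment$flow[keep]           # expiratory magnitude
  dt <- 1 / segment$sample_rate
  cumvol <- cumsum(flow) * dt
  if (min(diff(c(0, cumvol))) < -1e-6) {
    stop("maneuver rejected: cumulative expired volume is not monotone",
         call. = FALSE)
  }
  vmax <- max(cumvol)
  if (vmax < 1e-3) {
    stop("maneuver rejected: no expired volume (zero-flow segment)",
         call. = FALSE)
  }
  # drop flat (fully emptied) duplicates for interpolation
  ok <- c(TRUE, diff(cumvol) > 1e-9)
  grid <- seq(0, vmax, length.out = n_grid)
  f <- stats::approx(c(0, cumvol[ok]), c(flow[1], flow[ok]), xout = grid,
                     rule = 2)$y
  structure(list(expired_volume = grid, expiratory_flow = pmax(f, 0),
                 maneuver_id = maneuver_id),
            class = "flow_volume_loop")
}

#' @export
print.flow_volume_loop <- function(x, ...) {
  cat(sprintf("Flow-volume loop: %d points, expired volume %.3f L, peak flow %.2f L/s\n",
              length(x$expired_volume), max(x$expired_volume),
              max(x$expiratory_flow)))
  invisible(x)
}

#' Detect expiratory flow limitation by loop superposition
#'
#' Algorithmic version of the bedside criterion: flow limitation is present
#' when all or part of the expiratory flow during manual compression of the
#' abdomen is superimposed on the passive loop. A grid point counts as
#' superimposed when |compressed - passive| <= max(tol_abs,
#' tol_rel * passive); the diagnosis requires a contiguous superimposed run
#' covering at least `min_fraction` of the overlapping expired-volume range
#' (scattered tangential crossings do not qualify).
#'
#' @param passive,compressed [build_loop()] results for the paired
#'   maneuvers.
#' @param tol_abs Absolute flow tolerance, L/s (default 0.02).
#' @param tol_rel Relative tolerance as a fraction of the passive flow
#'   (default 0.05).
#' @param min_fraction Minimum contiguous superimposed fraction of the
#'   overlapping volume range (default 0.20).
#' @param n_grid Comparison grid resolution.
#' @return A list with `flow_limited` (logical) and `superimposed_fraction`
#'   (largest contiguous superimposed fraction of the overlap).
#' @export
detect_flow_limitation <- function(passive, compressed, tol_abs = 0.02,
                                   tol_rel = 0.05, min_fraction = 0.20,
                                   n_grid = 200) {
  stopifnot(inherits(passive, "flow_volume_loop"),
            inherits(compressed, "flow_volume_loop"))
  v_max <- min(max(passive$expired_volume), max(compressed$expired_volume))
  if (v_max <= 0) {
    stop("undeterminable: loops have no overlapping expired-volume range",
         call. = FALSE)
  }
  grid <- seq(0, v_max, length.out = n_grid)
  fp <- stats::approx(passive$expired_volume, passive$expiratory_flow,
                      xout = grid, rule = 2)$y
  fc <- stats::approx(compressed$expired_volume, compressed$expiratory_flow,
                      xout = grid, rule = 2)$y
  sup <- abs(fc - fp) <= pmax(tol_abs, tol_rel * fp)
  runs <- rle(sup)
  frac <- if (any(runs$values)) max(runs$lengths[runs$values]) / n_grid else 0
  list(flow_limited = frac >= min_fraction, superimposed_fraction = frac)
}

#' Patient-level flow-limitation classification
#'
#' The maneuver is repeated three times; a patient is classified as flow
#' limited only when flow limitation is confirmed in all three.
#'
#' @param results Logical vector of exactly three per-maneuver outcomes (or
#'   a list of [detect_flow_limitation()] results).
#' @return `TRUE` or `FALSE`.
#' @export
classify_patient_fl <- function(results) {
  if (is.list(results)) {
    results <- vapply(results, function(r) {
      if (is.list(r)) r$flow_limited else as.logical(r)
    }, TRUE)
  }
  if (length(results) != 3) stop("exactly three maneuvers required", call. = FALSE)
  all(results)
}
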