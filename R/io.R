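#' Write a waveform recording to CSV
#'
#' Columns: `time_s`, `paw_cmh2o`, `flow_lps`, `volume_l`, `phase`.
#'
#' @param recording A [waveform_recording].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_waveform_csv <- function(recording, path) {
  stopifnot(inherits(recording, "waveform_recording"))
  utils::write.csv(as.data.frame(recording), path, row.names = FALSE)
  invisible(path)
}

#' Read a waveform recording from CSV
#'
#' @param path CSV written by [write_waveform_csv()] (columns `time_s`,
#'   `paw_cmh2o`, `flow_lps`, `volume_l`, `phase`).
#' @return A [waveform_recording].
#' @export
read_waveform_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "paw_cmh2o", "flow_lps", "volume_l", "phase")
  missing <- setdiff(need, names(d))
  if (length(missing) > 0) {
    stop("malformed waveform CSV, missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (nrow(d) < 2) stop("waveform CSV has fewer than two samples", call. = FALSE)
  dt <- diff(d$time_s)
  if (any(dt <= 0) || max(abs(dt - dt[1])) > 1e-6) {
    stop("waveform CSV time base is not uniformly increasing", call. = FALSE)
  }
  new_recording(time = d$time_s, paw = d$paw_cmh2o, flow = d$flow_lps,
                volume = d$volume_l, phase = d$phase,
                sample_rate = 1 / dt[1])
}

#' Write a study analysis dataset to CSV
#'
#' @param data The `data` frame of a [run_study()] result (or the result
#'   itself).
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_cohort_csv <- function(data, path) {
  if (inherits(data, "study_result")) data <- data$data
  stopifnot(is.data.frame(data))
  out <- data
  out$label <- as.character(out$label)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read a study analysis dataset from CSV
#'
#' @param path CSV written by [write_cohort_csv()].
#' @return A data frame with `label` restored as a factor
#'   (complete/high/low) and logical columns restored.
#' @export
read_cohort_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"id" %in% names(d)) {
    stop("malformed cohort CSV: no id column", call. = FALSE)
  }
  if ("label" %in% names(d)) {
    d$label <- factor(d$label, levels = c("complete", "high", "low"))
  }
  for (nm in intersect(c("female", "chronic_pulmonary_disease",
                         "acute_pulmonary_disease", "smoking_history",
                         "supine", "flow_limited", "flow_limited_true",
                         "eligible", "valid"), names(d))) {
    d[[nm]] <- as.logical(d[[nm]])
  }
  d
}
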