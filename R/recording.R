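#' Continuous multichannel EEG recording
#'
#' Container for continuous EEG: a channels x samples matrix in microvolts,
#' a sampling rate, and stimulus event markers. Sample indices in `events`
#' are 0-based (sample 0 is the first sample); BrainVision's 1-based marker
#' positions are converted on read/write.
#'
#' @param data numeric matrix, channels x samples (microvolts). Row names,
#'   if present, are used as channel labels when `channel_labels` is `NULL`.
#' @param sampling_rate sampling rate in Hz.
#' @param events data frame with columns `sample_index` (0-based integer),
#'   `condition` (`"target"`, `"nontarget"`, or `NA` for unmapped codes)
#'   and `code` (marker string). May have zero rows.
#' @param channel_labels character vector of channel labels.
#' @return an object of class `continuous_recording`.
#' @export
continuous_recording <- function(data, sampling_rate, events = NULL,
                                 channel_labels = NULL) {
  stop_if_not(is.matrix(data) && is.numeric(data), "`data` must be a numeric matrix")
  if (is.null(channel_labels)) channel_labels <- rownames(data)
  stop_if_not(!is.null(channel_labels) && length(channel_labels) == nrow(data),
              "channel labels missing or wrong length")
  rownames(data) <- channel_labels
  stop_if_not(length(sampling_rate) == 1 && sampling_rate > 0,
              "sampling_rate must be a single positive number")
  if (is.null(events)) {
    events <- data.frame(sample_index = integer(), condition = character(),
                         code = character(), stringsAsFactors = FALSE)
  }
  stop_if_not(all(c("sample_index", "condition", "code") %in% names(events)),
              "events must have columns sample_index, condition, code")
  if (nrow(events)) {
    stop_if_not(all(events$sample_index >= 0) &&
                  all(events$sample_index < ncol(data)),
                "event sample indices must lie within [0, n_samples)")
    stop_if_not(!is.unsorted(events$sample_index, strictly = TRUE),
                "event sample indices must be strictly increasing")
  }
  structure(list(data = data, sampling_rate = sampling_rate, events = events),
            class = "continuous_recording")
}

#' @export
print.continuous_recording <- function(x, ...) {
  cat(sprintf("<continuous_recording> %d channels x %d samples @ %g Hz (%.1f s), %d events\n",
              nrow(x$data), ncol(x$data), x$sampling_rate,
              ncol(x$data) / x$sampling_rate, nrow(x$events)))
  cat("  channels:", paste(rownames(x$data), collapse = ", "), "\n")
  invisible(x)
}

n_samples <- function(rec) ncol(rec$data)
channel_labels <- function(rec) rownames(rec$data)

#' Default marker code map
#'
#' BrainVision stimulus codes are site-specific; the default convention maps
#' `"S  1"` to non-target and `"S  2"` to target.
#' @return named character vector: names are marker codes, values conditions.
#' @export
default_marker_map <- function() {
  c("S  1" = "nontarget", "S  2" = "target")
}
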