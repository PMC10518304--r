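# Subject-level averaging, grand averages, and P300 peak measurement.

new_subject_erp <- function(waveforms, time, n_epochs, subject_id) {
  structure(list(waveforms = waveforms, time = time, n_epochs = n_epochs,
                 subject_id = subject_id),
            class = "subject_erp")
}

#' @export
print.subject_erp <- function(x, ...) {
  cat(sprintf("<subject_erp> %s: conditions %s, channels %s, %d samples\n",
              x$subject_id, paste(dimnames(x$waveforms)[[1]], collapse = "/"),
              paste(dimnames(x$waveforms)[[2]], collapse = "/"),
              length(x$time)))
  cat("  epochs per condition:",
      paste(sprintf("%s=%d", names(x$n_epochs), x$n_epochs), collapse = ", "), "\n")
  invisible(x)
}

#' Average retained epochs into a subject ERP
#'
#' Arithmetic mean over retained epochs, per condition and channel.
#'
#' @param epochs an `epoch_set` (rejected and equalized upstream).
#' @return a `subject_erp`: `waveforms` is a condition x channel x time
#'   array, `n_epochs` the retained count per condition.
#' @export
average_epochs <- function(epochs) {
  conds <- sort(unique(epochs$condition))
  labels <- dimnames(epochs$data)[[2]]
  nt <- dim(epochs$data)[3]
  w <- array(NA_real_, c(length(conds), length(labels), nt),
             dimnames = list(conds, labels, NULL))
  n_epochs <- setNames(integer(length(conds)), conds)
  for (co in conds) {
    sel <- epochs$retained & epochs$condition == co
    stop_if_not(sum(sel) >= 1, "no retained epochs for condition %s", co)
    n_epochs[co] <- sum(sel)
    w[co, , ] <- colMeans(epochs$data[sel, , , drop = FALSE], dims = 1)
  }
  new_subject_erp(w, epochs$time, n_epochs, epochs$subject_id)
}

#' Grand-average ERPs across subjects
#'
#' Unweighted mean over subjects: each subject contributes with weight one
#' regardless of how many epochs entered their average.
#'
#' @param erps list of `subject_erp` objects on a common time axis.
#' @return a `subject_erp` whose `n_epochs` holds the subject count.
#' @export
grand_average <- function(erps) {
  stop_if_not(length(erps) >= 1, "need at least one subject ERP")
  w <- erps[[1]]$waveforms
  if (length(erps) > 1) {
    for (e in erps[-1]) w <- w + e$waveforms
    w <- w / length(erps)
  }
  new_subject_erp(w, erps[[1]]$time,
                  setNames(rep(length(erps), nrow(w)), rownames(w)),
                  sprintf("grand_average_n%d", length(erps)))
}

#' Measure the P300 peak
#'
#' Maximum peak amplitude and its latency in the closed measurement window
#' (default 300-600 ms; boundary samples are eligible, ties resolve to the
#' earliest sample). `local = TRUE` restricts the search to local maxima
#' (falling back to the global maximum when the window contains none).
#'
#' @param erp a `subject_erp`.
#' @param window closed window in ms.
#' @param channels channels to measure; defaults to the midline EEG sites
#'   (all non-EOG channels when none of Fz/Cz/Pz is present).
#' @param local use local-peak detection instead of the global maximum.
#' @return data frame with columns `subject_id`, `condition`, `channel`,
#'   `amplitude`, `latency`.
#' @export
measure_peak <- function(erp, window = c(300, 600), channels = NULL,
                         local = FALSE) {
  widx <- which(erp$time >= window[1] & erp$time <= window[2])
  stop_if_not(length(widx) > 0, "measurement window outside the epoch time axis")
  if (is.null(channels)) {
    channels <- intersect(c("Fz", "Cz", "Pz"), colnames(erp$waveforms))
    if (!length(channels)) channels <- setdiff(colnames(erp$waveforms), "EOG")
  }
  out <- list()
  for (co in rownames(erp$waveforms)) {
    for (ch in channels) {
      w <- erp$waveforms[co, ch, widx]
      pick <- which.max(w)
      if (local) {
        n <- length(w)
        interior <- seq_along(w) > 1 & seq_along(w) < n
        is_local <- which(interior & w > c(Inf, w[-n]) & w >= c(w[-1], Inf))
        if (length(is_local)) pick <- is_local[which.max(w[is_local])]
      }
      out[[length(out) + 1]] <- data.frame(
        subject_id = erp$subject_id, condition = co, channel = ch,
        amplitude = unname(w[pick]), latency = unname(erp$time[widx][pick]),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
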