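# Epoching, baseline correction, automatic artifact rejection, and epoch
# count equalization between conditions.

#' Automatic epoch rejection criteria
#'
#' The four standard analyzer criteria: (a) maximum absolute amplitude
#' +/- 70 microvolts, (b) maximum voltage step 50 microvolts/ms between
#' adjacent samples, (c) maximum peak-to-peak difference 50 microvolts in
#' any sliding 200 ms window, (d) lowest activity 0.5 microvolts in any
#' sliding 100 ms window (flatline detection).
#'
#' @param max_abs,max_step,max_range,min_activity thresholds, all strictly
#'   positive; units as above.
#' @return a `rejection_criteria` list.
#' @export
rejection_criteria <- function(max_abs = 70, max_step = 50, max_range = 50,
                               min_activity = 0.5) {
  stop_if_not(max_abs > 0 && max_step > 0 && max_range > 0 && min_activity > 0,
              "all rejection thresholds must be strictly positive")
  structure(list(max_abs = max_abs, max_step = max_step,
                 max_range = max_range, min_activity = min_activity),
            class = "rejection_criteria")
}

new_epoch_set <- function(data, time, condition, retained, subject_id,
                          sampling_rate, rejection_counts = NULL) {
  structure(list(data = data, time = time, condition = condition,
                 retained = retained, subject_id = subject_id,
                 sampling_rate = sampling_rate,
                 rejection_counts = rejection_counts),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d epochs (%d retained) x %d channels x %d samples [%g, %g] ms\n",
              dim(x$data)[1], sum(x$retained), dim(x$data)[2], dim(x$data)[3],
              min(x$time), max(x$time)))
  print(table(condition = x$condition, retained = x$retained))
  invisible(x)
}

#' Segment a recording into stimulus-locked epochs
#'
#' One epoch per event over `window` (default 1000 ms including the 200 ms
#' pre-stimulus period: a half-open window from -200 ms up to, not
#' including, +800 ms, i.e. 500 samples at 500 Hz with time axis
#' -200, -198, ..., 798). Events without full window support are dropped
#' with a warning.
#'
#' @param rec a [continuous_recording()].
#' @param window epoch window in ms relative to stimulus onset, half-open.
#' @param subject_id carried into the epoch set.
#' @return an `epoch_set` with fields `data` (epochs x channels x time),
#'   `time` (ms), `condition`, `retained`.
#' @export
epoch_data <- function(rec, window = c(-200, 800), subject_id = "") {
  fs <- rec$sampling_rate
  n_pre <- as.integer(round(-window[1] / 1000 * fs))
  n_post <- as.integer(round(window[2] / 1000 * fs))
  rel <- seq(-n_pre, n_post - 1L)
  time <- rel / fs * 1000
  ev <- rec$events
  stop_if_not(nrow(ev) > 0, "recording has no events")
  onset_r <- ev$sample_index + 1L               # 0-based -> R index of t = 0
  ok <- onset_r - n_pre >= 1 & onset_r + n_post - 1L <= n_samples(rec)
  if (any(!ok)) {
    warning(sprintf("%d event(s) too close to the recording edge were dropped",
                    sum(!ok)))
  }
  ev <- ev[ok, , drop = FALSE]
  onset_r <- onset_r[ok]
  stop_if_not(nrow(ev) > 0, "no event has full epoch support")
  idx <- outer(onset_r, rel, `+`)               # epochs x time
  nch <- nrow(rec$data)
  data <- array(NA_real_, c(nrow(ev), nch, length(rel)),
                dimnames = list(NULL, rownames(rec$data), NULL))
  for (ch in seq_len(nch)) {
    data[, ch, ] <- rec$data[ch, ][idx]
  }
  new_epoch_set(data, time, ev$condition, rep(TRUE, nrow(ev)), subject_id, fs)
}

#' Baseline-correct epochs
#'
#' Subtracts, per epoch and channel, the mean over the pre-stimulus baseline
#' window (default the 200 ms before onset, half-open at 0).
#'
#' @param epochs an `epoch_set`.
#' @param baseline window in ms, half-open.
#' @return the corrected `epoch_set`.
#' @export
baseline_correct <- function(epochs, baseline = c(-200, 0)) {
  bidx <- which(epochs$time >= baseline[1] & epochs$time < baseline[2])
  stop_if_not(length(bidx) > 0, "baseline window contains no samples")
  bl <- rowMeans(epochs$data[, , bidx, drop = FALSE], dims = 2)
  epochs$data <- epochs$data - array(bl, dim(epochs$data))
  epochs
}

# Running max/min over sliding windows of w samples, vectorized across rows
# by the doubling (sparse-table) construction. m: traces x time. Returns
# traces x (time - w + 1).
running_extreme <- function(m, w, fun = pmax) {
  n <- ncol(m)
  stop_if_not(w <= n, "window longer than trace")
  r <- m; k <- 1L
  while (2L * k <= w) {
    nc <- ncol(r)
    r <- fun(r[, 1:(nc - k), drop = FALSE], r[, (k + 1):nc, drop = FALSE])
    k <- 2L * k
  }
  if (k < w) {
    r <- fun(r[, 1:(n - w + 1), drop = FALSE],
             r[, (w - k + 1):(n - k + 1), drop = FALSE])
  }
  r
}

#' Reject artifact-contaminated epochs
#'
#' An epoch is rejected when ANY tested channel violates ANY criterion of
#' [rejection_criteria()]. Windows slide over every offset; the voltage step
#' is the adjacent-sample difference divided by the sample interval. The EOG
#' channel is excluded from testing (ocular activity legitimately exceeds
#' the thresholds and is removed upstream by ICA).
#'
#' @param epochs a baseline-corrected `epoch_set`.
#' @param criteria a [rejection_criteria()].
#' @param channels channels to test (default all but `exclude`).
#' @param exclude channels excluded from testing.
#' @return the `epoch_set` with its `retained` mask updated and a
#'   `rejection_counts` field (epochs newly rejected per criterion,
#'   non-exclusive).
#' @export
reject_artifacts <- function(epochs, criteria = rejection_criteria(),
                             channels = NULL, exclude = "EOG") {
  labels <- dimnames(epochs$data)[[2]]
  channels <- channels %||% setdiff(labels, exclude)
  d <- epochs$data[, channels, , drop = FALSE]
  ne <- dim(d)[1]; nch <- dim(d)[2]; nt <- dim(d)[3]
  m <- matrix(aperm(d, c(1, 2, 3)), nrow = ne * nch, ncol = nt)
  dt_ms <- 1000 / epochs$sampling_rate
  w_range <- as.integer(round(200 / dt_ms))
  w_act <- as.integer(round(100 / dt_ms))

  viol_a <- matrixize <- function(v) matrix(v, ne, nch)
  a <- rowSums(abs(m) > criteria$max_abs) > 0
  b <- rowSums(abs(m[, -1, drop = FALSE] - m[, -nt, drop = FALSE]) / dt_ms >
                 criteria$max_step) > 0
  rmax <- running_extreme(m, w_range, pmax)
  rmin <- running_extreme(m, w_range, pmin)
  cc <- rowSums(rmax - rmin > criteria$max_range) > 0
  amax <- running_extreme(m, w_act, pmax)
  amin <- running_extreme(m, w_act, pmin)
  dd <- rowSums(amax - amin < criteria$min_activity) > 0

  per_epoch <- function(v) rowSums(matrix(v, ne, nch)) > 0
  va <- per_epoch(a); vb <- per_epoch(b); vc <- per_epoch(cc); vd <- per_epoch(dd)
  bad <- va | vb | vc | vd
  newly <- epochs$retained & bad
  epochs$rejection_counts <- c(max_abs = sum(va & epochs$retained),
                               max_step = sum(vb & epochs$retained),
                               max_range = sum(vc & epochs$retained),
                               min_activity = sum(vd & epochs$retained),
                               rejected = sum(newly))
  epochs$retained <- epochs$retained & !bad
  epochs
}

#' Randomly equalize epoch counts between conditions
#'
#' The condition with more retained epochs is subsampled at random (seeded,
#' without replacement) down to the smaller count, so both conditions
#' contribute equally to the average.
#'
#' @param epochs an `epoch_set`.
#' @param seed integer seed.
#' @return the `epoch_set` with an updated `retained` mask.
#' @export
equalize_epoch_counts <- function(epochs, seed = 1) {
  set.seed(seed)
  conds <- unique(epochs$condition)
  counts <- vapply(conds, function(co) sum(epochs$retained & epochs$condition == co),
                   numeric(1))
  stop_if_not(all(counts > 0),
              "condition with zero retained epochs: %s",
              paste(conds[counts == 0], collapse = ", "))
  target <- min(counts)
  for (co in conds) {
    idx <- which(epochs$retained & epochs$condition == co)
    if (length(idx) > target) {
      drop <- sample(idx, length(idx) - target)
      epochs$retained[drop] <- FALSE
    }
  }
  epochs
}

#' Check the minimum retained epoch count
#'
#' @param epochs an `epoch_set`.
#' @param minimum minimum retained epochs per condition (default 20).
#' @return named logical vector, one entry per condition.
#' @export
check_min_epochs <- function(epochs, minimum = 20) {
  conds <- unique(epochs$condition)
  setNames(vapply(conds, function(co) {
    sum(epochs$retained & epochs$condition == co) >= minimum
  }, logical(1)), conds)
}
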