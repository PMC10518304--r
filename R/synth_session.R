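# Single-session synthesis: event sequence and continuous-recording renderer.

#' Generate an oddball stimulus sequence
#'
#' Exactly `round(n_stimuli * p_target)` targets (40 at defaults) are placed
#' by a seeded uniform shuffle among the non-targets (or per-trial Bernoulli
#' draws when `cfg$bernoulli_targets`). Onset times accumulate
#' inter-stimulus intervals drawn uniformly from `cfg$isi_range`.
#'
#' @param cfg a [session_config()].
#' @param seed integer seed.
#' @return data frame with columns `sample_index` (0-based), `onset_s`,
#'   `condition`, `code`.
#' @export
generate_event_sequence <- function(cfg = session_config(), seed = 1) {
  set.seed(seed)
  n <- cfg$n_stimuli
  if (isTRUE(cfg$bernoulli_targets)) {
    is_target <- rbinom(n, 1, cfg$p_target) == 1
  } else {
    n_t <- round(n * cfg$p_target)
    is_target <- sample(rep(c(TRUE, FALSE), c(n_t, n - n_t)))
  }
  isi <- runif(n, cfg$isi_range[1], cfg$isi_range[2])
  onset <- cumsum(isi)
  code_map <- default_marker_map()
  condition <- ifelse(is_target, "target", "nontarget")
  data.frame(
    sample_index = as.integer(round(onset * cfg$sampling_rate)),
    onset_s = onset,
    condition = condition,
    code = names(code_map)[match(condition, code_map)],
    stringsAsFactors = FALSE)
}

# 1/f-amplitude-shaped Gaussian noise, scaled to a target sd.
.noise_shape_cache <- new.env(parent = emptyenv())

pink_noise <- function(n, sd_target, exponent = 1) {
  if (sd_target <= 0) return(numeric(n))
  m <- nextn(n, c(2L, 3L, 5L))
  key <- paste(m, exponent, sep = "_")
  shape <- .noise_shape_cache[[key]]
  if (is.null(shape)) {
    f <- c(1, seq_len(m - 1))          # DC bin reused as f=1 then zeroed
    f <- pmin(f, m - f + 1)            # two-sided spectrum
    shape <- 1 / f^(exponent / 2)
    shape[1] <- 0
    if (length(ls(.noise_shape_cache)) > 16) rm(list = ls(.noise_shape_cache),
                                                envir = .noise_shape_cache)
    .noise_shape_cache[[key]] <- shape
  }
  # white Gaussian spectrum shaped by 1/f^(exponent/2); one inverse FFT
  spec <- complex(real = rnorm(m), imaginary = rnorm(m)) * shape
  x <- Re(fft(spec, inverse = TRUE)) / sqrt(m)
  x <- x[seq_len(n)]
  x * sd_target / sd(x)
}

# ~300 ms biphasic blink transient, unit peak amplitude.
blink_template <- function(sampling_rate) {
  t <- seq(-0.15, 0.15, by = 1 / sampling_rate)
  w <- exp(-t^2 / (2 * 0.05^2)) - 0.35 * exp(-(t - 0.06)^2 / (2 * 0.08^2))
  w / max(w)
}

#' Render a continuous recording for one subject
#'
#' Each EEG channel is the sum of 1/f background noise, a random-phase 10 Hz
#' alpha component, one condition- and channel-specific Gaussian P300 bump
#' per stimulus, and propagated blink transients. The EOG channel carries
#' full-amplitude blinks plus its own noise and no ERP.
#'
#' @param params a [subject_erp_params()].
#' @param events event data frame from [generate_event_sequence()].
#' @param cfg a [session_config()].
#' @param seed integer seed.
#' @return a [continuous_recording()].
#' @export
render_subject_recording <- function(params, events, cfg = session_config(),
                                     seed = 1) {
  set.seed(seed)
  fs <- cfg$sampling_rate
  nz <- params$noise
  n <- max(events$sample_index) + 1 + as.integer(2 * fs)
  stop_if_not(all(events$sample_index < n), "events beyond session duration")
  eeg_ch <- eeg_channels(cfg)
  t_all <- seq_len(n) / fs

  # blink train (shared across channels)
  blink_sig <- numeric(n)
  n_blinks <- 0L
  if (nz$blink_rate > 0 && nz$blink_amplitude_eog != 0) {
    dur_min <- n / fs / 60
    n_blinks <- rpois(1, nz$blink_rate * dur_min)
    tpl <- blink_template(fs)
    half <- (length(tpl) - 1) / 2
    if (n_blinks > 0) {
      centers <- sort(as.integer(runif(n_blinks, half + 1, n - half)))
      for (cc in centers) {
        idx <- (cc - half):(cc + half)
        blink_sig[idx] <- blink_sig[idx] + tpl
      }
    }
  }

  sigma_samp <- params$width_ms / 2.355 / 1000 * fs
  ep_len <- as.integer(cfg$stim_duration_ms / 1000 * fs)
  rel <- 0:(ep_len - 1)

  data <- matrix(0, nrow = length(cfg$channels), ncol = n,
                 dimnames = list(cfg$channels, NULL))
  for (ch in eeg_ch) {
    x <- pink_noise(n, nz$background_noise_sd)
    if (nz$alpha_power > 0) {
      x <- x + nz$alpha_power * sin(2 * pi * 10 * t_all + runif(1, 0, 2 * pi))
    }
    prop <- nz$eog_propagation[ch]
    if (!is.na(prop) && prop != 0) {
      x <- x + prop * nz$blink_amplitude_eog * blink_sig
    }
    for (k in seq_len(nrow(events))) {
      cond <- events$condition[k]
      amp <- params$amplitude[cond, ch]
      if (is.na(amp) || amp == 0) next
      lat_samp <- params$latency[cond, ch] / 1000 * fs
      onset <- events$sample_index[k] + 1
      idx <- onset + rel
      keep <- idx <= n
      x[idx[keep]] <- x[idx[keep]] +
        amp * exp(-(rel[keep] - lat_samp)^2 / (2 * sigma_samp^2))
    }
    data[ch, ] <- x
  }
  data[cfg$eog_channel, ] <- nz$blink_amplitude_eog * blink_sig +
    pink_noise(n, nz$eog_noise_sd)

  continuous_recording(data, fs, events[, c("sample_index", "condition", "code")])
}

#' Behavioral count-accuracy criterion
#'
#' Passes when the reported mental count is within 10 percent of the true
#' target count.
#'
#' @param reported,true non-negative counts (vectorized).
#' @param tolerance allowed relative error rate.
#' @return logical vector.
#' @export
check_count_accuracy <- function(reported, true, tolerance = 0.10) {
  stop_if_not(all(reported >= 0) && all(true >= 0), "counts must be non-negative")
  stop_if_not(all(true > 0), "true count must be positive")
  abs(reported - true) / true <= tolerance
}
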