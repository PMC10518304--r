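#' Oddball session configuration
#'
#' Defaults reproduce the study design: 120 stimuli, target probability 0.33,
#' inter-stimulus intervals uniform in 3-7 s, 1000 ms stimulation, 500 Hz
#' sampling, midline electrodes Fz/Cz/Pz plus one EOG channel.
#'
#' @param n_stimuli number of stimuli per session.
#' @param p_target probability of the deviant (target) stimulus.
#' @param isi_range inter-stimulus interval range in seconds.
#' @param stim_duration_ms stimulus duration in ms.
#' @param sampling_rate sampling rate in Hz.
#' @param channels channel labels; EOG must be last unless `eog_channel` set.
#' @param eog_channel label of the EOG channel.
#' @param bernoulli_targets if `TRUE`, draw target assignment per trial as a
#'   Bernoulli(p_target); the default fixes the target count at
#'   `round(n_stimuli * p_target)` and shuffles positions.
#' @return a `session_config` list.
#' @export
session_config <- function(n_stimuli = 120L, p_target = 0.33,
                           isi_range = c(3, 7), stim_duration_ms = 1000,
                           sampling_rate = 500,
                           channels = c("Fz", "Cz", "Pz", "EOG"),
                           eog_channel = "EOG",
                           bernoulli_targets = FALSE) {
  stop_if_not(n_stimuli >= 1, "n_stimuli must be >= 1")
  stop_if_not(p_target > 0 && p_target < 1, "p_target must be in (0, 1)")
  stop_if_not(isi_range[1] <= isi_range[2] && isi_range[1] > 0,
              "invalid isi_range")
  stop_if_not(eog_channel %in% channels, "eog_channel not among channels")
  structure(list(n_stimuli = as.integer(n_stimuli), p_target = p_target,
                 isi_range = isi_range, stim_duration_ms = stim_duration_ms,
                 sampling_rate = sampling_rate, channels = channels,
                 eog_channel = eog_channel,
                 bernoulli_targets = bernoulli_targets),
            class = "session_config")
}

eeg_channels <- function(cfg) setdiff(cfg$channels, cfg$eog_channel)

#' Noise and artifact model for a simulated subject
#'
#' Background activity is 1/f-shaped noise plus a 10 Hz alpha sinusoid with
#' random phase; blinks are Poisson-timed ~300 ms biphasic transients,
#' full-amplitude on the EOG channel and propagated to the EEG channels with
#' per-channel weights. Amplitudes chosen so frontal blink artifacts reach
#' the tens-of-microvolts range seen in real recordings.
#'
#' @param background_noise_sd sd (microvolts) of the 1/f background per EEG
#'   channel, before any filtering.
#' @param alpha_power amplitude (microvolts) of the 10 Hz component.
#' @param blink_rate blinks per minute.
#' @param blink_amplitude_eog blink peak on the EOG channel (microvolts).
#' @param eog_propagation named weights (fraction of EOG blink amplitude)
#'   for each EEG channel.
#' @param eog_noise_sd sd of the EOG channel's own background noise.
#' @return a `noise_model` list.
#' @export
noise_model <- function(background_noise_sd = 4, alpha_power = 1.5,
                        blink_rate = 6, blink_amplitude_eog = 250,
                        eog_propagation = c(Fz = 0.4, Cz = 0.2, Pz = 0.08),
                        eog_noise_sd = 3) {
  structure(list(background_noise_sd = background_noise_sd,
                 alpha_power = alpha_power, blink_rate = blink_rate,
                 blink_amplitude_eog = blink_amplitude_eog,
                 eog_propagation = eog_propagation,
                 eog_noise_sd = eog_noise_sd),
            class = "noise_model")
}

#' Per-subject ERP ground-truth parameters
#'
#' @param latency,amplitude numeric matrices condition x channel
#'   (rows `target`/`nontarget`, columns the EEG channels): P300 peak
#'   latency (ms post-stimulus) and peak amplitude (microvolts).
#' @param width_ms template full width at half maximum in ms (the Gaussian
#'   bump has sd `width_ms / 2.355`).
#' @param noise a [noise_model()].
#' @return a `subject_erp_params` list.
#' @export
subject_erp_params <- function(latency, amplitude, width_ms = 120,
                               noise = noise_model()) {
  stop_if_not(all(latency > 0), "latencies must be positive")
  stop_if_not(all(amplitude >= 0), "amplitudes must be >= 0")
  stop_if_not(width_ms > 0, "width must be positive")
  structure(list(latency = latency, amplitude = amplitude,
                 width_ms = width_ms, noise = noise),
            class = "subject_erp_params")
}

#' Group-level generative model for a simulated cohort
#'
#' Defaults calibrate every group x condition x channel P300 mean/sd cell and
#' every neuropsychological score to the published group summaries
#' ([p300_reference()], [neuropsych_reference()], [behavior_reference()]).
#' Neuropsychological scores are coupled to the subject's latent P300
#' latency/amplitude factors through a Gaussian copula with the stated
#' marginal means/sds (single-factor loadings, positive semi-definite by
#' construction).
#'
#' @param n_subjects named vector: subjects per group.
#' @param p300 data frame in the layout of [p300_reference()].
#' @param neuropsych data frame in the layout of [neuropsych_reference()].
#' @param behavior data frame in the layout of [behavior_reference()]; the
#'   count-report error sd (and bias) differs by group.
#' @param coupling named list: score name -> c(latency = r, amplitude = r)
#'   correlations between that score and the latent factors. Unlisted scores
#'   are uncoupled.
#' @param within_subject_corr correlation between a subject's latent factor
#'   and each of their six per-cell deviations (controls how strongly the
#'   six cells co-vary within a subject).
#' @param latency_bounds truncation bounds (ms) for per-cell latencies.
#' @param min_amplitude floor (microvolts) for per-cell amplitudes.
#' @param width_ms ERP template FWHM in ms.
#' @param noise a [noise_model()].
#' @param enforce_gds_cutoff if `TRUE`, resample MCI subjects whose simulated
#'   GDS exceeds 11 (the study's depression exclusion). Off by default: the
#'   published MCI GDS spread (8.20 +/- 5.31) implies scores above 11 in the
#'   analyzed sample.
#' @return a `group_model` list.
#' @export
group_model <- function(n_subjects = c(HC = 20L, MCI = 20L),
                        p300 = p300_reference(),
                        neuropsych = neuropsych_reference(),
                        behavior = behavior_reference(),
                        coupling = list(),
                        within_subject_corr = 0.8,
                        latency_bounds = c(250, 700),
                        min_amplitude = 0.5,
                        width_ms = 120,
                        noise = noise_model(),
                        enforce_gds_cutoff = FALSE) {
  stop_if_not(all(p300$sd >= 0) && all(neuropsych$hc_sd >= 0) &&
                all(neuropsych$mci_sd >= 0), "sds must be >= 0")
  stop_if_not(abs(within_subject_corr) <= 1, "within_subject_corr must be in [-1, 1]")
  for (nm in names(coupling)) {
    cl <- coupling[[nm]]
    cl_l <- unname(cl["latency"] %||% 0); if (is.na(cl_l)) cl_l <- 0
    cl_a <- unname(cl["amplitude"] %||% 0); if (is.na(cl_a)) cl_a <- 0
    stop_if_not(abs(cl_l) <= 1 && abs(cl_a) <= 1,
                "coupling for %s outside [-1, 1]", nm)
    stop_if_not(cl_l^2 + cl_a^2 <= 1,
                "infeasible coupling for %s: latency^2 + amplitude^2 > 1", nm)
  }
  structure(list(n_subjects = n_subjects, p300 = p300,
                 neuropsych = neuropsych, behavior = behavior,
                 coupling = coupling,
                 within_subject_corr = within_subject_corr,
                 latency_bounds = latency_bounds,
                 min_amplitude = min_amplitude, width_ms = width_ms,
                 noise = noise, enforce_gds_cutoff = enforce_gds_cutoff),
            class = "group_model")
}
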