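# Cohort simulation: latent P300 parameters, coupled neuropsychological
# scores, behavioral count reports, and (optionally) rendered recordings.

draw_subject <- function(model, group, cfg, seed) {
  set.seed(seed)
  repeat {
    z_lat <- rnorm(1)
    z_amp <- rnorm(1)
    rho <- model$within_subject_corr
    eeg_ch <- eeg_channels(cfg)
    conds <- c("target", "nontarget")

    cell <- function(measure, z) {
      ref <- model$p300
      m <- matrix(NA_real_, 2, length(eeg_ch), dimnames = list(conds, eeg_ch))
      for (co in conds) for (ch in eeg_ch) {
        row <- ref[ref$group == group & ref$condition == co &
                     ref$channel == ch & ref$measure == measure, ]
        m[co, ch] <- row$mean + row$sd * (rho * z + sqrt(1 - rho^2) * rnorm(1))
      }
      m
    }
    latency <- cell("latency", z_lat)
    latency <- pmin(pmax(latency, model$latency_bounds[1]), model$latency_bounds[2])
    amplitude <- pmax(cell("amplitude", z_amp), model$min_amplitude)

    np <- model$neuropsych
    mcol <- if (group == "HC") "hc_mean" else "mci_mean"
    scol <- if (group == "HC") "hc_sd" else "mci_sd"
    scores <- numeric(nrow(np))
    names(scores) <- np$variable
    for (i in seq_len(nrow(np))) {
      cl <- model$coupling[[np$variable[i]]]
      c_l <- if (is.null(cl)) 0 else unname(cl["latency"] %||% 0)
      c_a <- if (is.null(cl)) 0 else unname(cl["amplitude"] %||% 0)
      if (is.na(c_l)) c_l <- 0
      if (is.na(c_a)) c_a <- 0
      z <- c_l * z_lat + c_a * z_amp + sqrt(1 - c_l^2 - c_a^2) * rnorm(1)
      v <- np[[mcol]][i] + np[[scol]][i] * z
      if (np$integer[i]) v <- round(v)
      if (!is.na(np$lower[i])) v <- max(v, np$lower[i])
      if (!is.na(np$upper[i])) v <- min(v, np$upper[i])
      scores[i] <- v
    }
    if (!isTRUE(model$enforce_gds_cutoff) || group == "HC" ||
        is.na(scores["GDS"]) || scores["GDS"] <= 11) break
    # resample subjects excluded by the depression cutoff
  }
  list(z_latency = z_lat, z_amplitude = z_amp,
       latency = latency, amplitude = amplitude, scores = scores)
}

#' Simulate a two-group oddball cohort
#'
#' Per subject: latent latency/amplitude factors are drawn from the group's
#' calibrated normal distributions (latencies truncated to
#' `model$latency_bounds`, amplitudes floored at `model$min_amplitude`);
#' neuropsychological scores are drawn jointly with the latents at the
#' configured couplings; the reported target count is the true count plus a
#' group-specific rounded error term; and, when `render = TRUE`, a
#' continuous recording is synthesized.
#'
#' @param model a [group_model()].
#' @param cfg a [session_config()].
#' @param seed master seed; per-subject streams are derived with
#'   [child_seed()], so subject `k`'s data do not depend on cohort size.
#' @param render render continuous recordings (set `FALSE` for fast
#'   measure-level simulation at large n).
#' @return list with `cohort` (a [cohort_table()]), `recordings` (named list
#'   of [continuous_recording()] or `NULL`), `params` (per-subject ground
#'   truth: latent factors, cell latencies/amplitudes, events, seed).
#' @export
simulate_cohort <- function(model = group_model(), cfg = session_config(),
                            seed = 1, render = TRUE) {
  groups <- names(model$n_subjects)
  recordings <- list()
  params <- list()
  rows <- list()
  counter <- 0L
  for (g in groups) {
    beh <- model$behavior[model$behavior$group == g, ]
    n_g <- model$n_subjects[[g]]
    sexes <- rep(c("F", "M"), c(round(n_g * 11 / 20), n_g - round(n_g * 11 / 20)))
    for (i in seq_len(n_g)) {
      counter <- counter + 1L
      id <- sprintf("%s%02d", tolower(g), i)
      sj_seed <- child_seed(seed, "subject", g, i)
      sj <- draw_subject(model, g, cfg, child_seed(sj_seed, "latents"))
      sj$width_ms <- model$width_ms
      events <- generate_event_sequence(cfg, child_seed(sj_seed, "events"))
      true_n <- sum(events$condition == "target")
      set.seed(child_seed(sj_seed, "behavior"))
      reported <- max(0L, true_n + as.integer(round(rnorm(1, beh$mean - beh$true_targets, beh$sd))))
      sj_params <- subject_erp_params(sj$latency, sj$amplitude,
                                      width_ms = model$width_ms,
                                      noise = model$noise)
      if (render) {
        recordings[[id]] <- render_subject_recording(
          sj_params, events, cfg, child_seed(sj_seed, "render"))
      }
      params[[id]] <- c(sj, list(events = events, seed = sj_seed,
                                 erp_params = sj_params))
      rows[[id]] <- data.frame(
        id = id, group = g,
        age = round(sj$scores["age"], 1),
        education = round(sj$scores["education"], 1),
        sex = sexes[i],
        reported_count = reported, true_target_count = true_n,
        as.list(sj$scores[setdiff(names(sj$scores), c("age", "education"))]),
        stringsAsFactors = FALSE, check.names = FALSE)
    }
  }
  cohort <- cohort_table(do.call(rbind, c(rows, list(make.row.names = FALSE))))
  list(cohort = cohort,
       recordings = if (render) recordings else NULL,
       params = params)
}
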