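# Shared builders for synthetic fixtures. Everything is generated in code;
# no stored binary data.

`%||%` <- function(a, b) if (is.null(a)) b else a

eeg_sites <- c("Fz", "Cz", "Pz")

cell_matrix <- function(target, nontarget) {
  matrix(c(rep(target, 3), rep(nontarget, 3)), nrow = 2, byrow = TRUE,
         dimnames = list(c("target", "nontarget"), eeg_sites))
}

silent_noise <- function() {
  noise_model(background_noise_sd = 0, alpha_power = 0, blink_rate = 0,
              eog_noise_sd = 0)
}

# a clean subject: flat topography, known latencies/amplitudes, no noise
noiseless_params <- function(lat_target = 450, lat_nontarget = 430,
                             amp_target = 6, amp_nontarget = 4) {
  subject_erp_params(cell_matrix(lat_target, lat_nontarget),
                     cell_matrix(amp_target, amp_nontarget),
                     noise = silent_noise())
}

# rejection criteria usable on noiseless data (the flatline criterion (d)
# exists to catch dead channels; exactly-zero synthetic baselines would
# otherwise reject every epoch)
noiseless_criteria <- function() rejection_criteria(min_activity = 1e-9)

# run_config for noiseless ground-truth recovery
noiseless_run_config <- function(seed = 1, n_hc = 2, n_mci = 2) {
  model <- group_model(n_subjects = c(HC = n_hc, MCI = n_mci),
                       noise = silent_noise())
  cfg <- run_config(seed = seed, model = model)
  cfg$preproc$ica <- FALSE
  cfg$preproc$criteria <- noiseless_criteria()
  cfg
}

# a recording made of explicit epoch traces placed at known onsets,
# for rejection/baseline tests: traces is a list of length-500 vectors
recording_from_epochs <- function(traces, fs = 500, channel = "Fz",
                                  conditions = NULL) {
  n_ep <- length(traces)
  gap <- 1500L
  n <- (n_ep + 1L) * gap
  x <- numeric(n)
  onsets <- integer(n_ep)
  for (i in seq_len(n_ep)) {
    onset <- i * gap               # 0-based sample of stimulus
    onsets[i] <- onset
    x[(onset + 1 - 100):(onset + 400)] <- traces[[i]]
  }
  conditions <- conditions %||% rep(c("target", "nontarget"), length.out = n_ep)
  data <- matrix(x, nrow = 1, dimnames = list(channel, NULL))
  ev <- data.frame(sample_index = onsets, condition = conditions,
                   code = ifelse(conditions == "target", "S  2", "S  1"))
  continuous_recording(data, fs, ev)
}

# long measure-level data frame for ANOVA tests: one row per
# subject x condition x channel; cells drawn around group/condition means
simulate_measures <- function(n_per_group = 10, effects = list(),
                              subject_sd = 40, cell_sd = 30, seed = 1) {
  set.seed(seed)
  subj <- sprintf("s%02d", seq_len(2 * n_per_group))
  grp <- rep(c("HC", "MCI"), each = n_per_group)
  d <- expand.grid(subject = subj, condition = c("target", "nontarget"),
                   channel = eeg_sites, stringsAsFactors = FALSE)
  d$group <- grp[match(d$subject, subj)]
  mu <- rep(450, nrow(d))
  for (ef in names(effects)) {
    mu <- mu + switch(ef,
      group = ifelse(d$group == "MCI", effects$group, 0),
      condition = ifelse(d$condition == "target", effects$condition, 0),
      interaction = ifelse(d$group == "MCI" & d$condition == "target",
                           effects$interaction, 0))
  }
  zs <- rnorm(length(subj)) * subject_sd
  d$value <- mu + zs[match(d$subject, subj)] + rnorm(nrow(d), 0, cell_sd)
  d
}

# Brute-force cell-means sum-of-squares partition for the balanced
# group x condition x channel mixed design (independent oracle for the
# ANOVA implementation).
anova_bruteforce <- function(d) {
  Y <- d$value
  g <- d$group; j <- d$condition; k <- d$channel; s <- d$subject
  gm <- mean(Y)
  m_g <- tapply(Y, g, mean); m_j <- tapply(Y, j, mean); m_k <- tapply(Y, k, mean)
  m_s <- tapply(Y, s, mean)
  m_gj <- tapply(Y, list(g, j), mean); m_gk <- tapply(Y, list(g, k), mean)
  m_jk <- tapply(Y, list(j, k), mean)
  m_gjk <- tapply(Y, list(g, j, k), mean)
  m_sj <- tapply(Y, list(s, j), mean); m_sk <- tapply(Y, list(s, k), mean)
  subj_group <- tapply(g, s, function(v) v[1])
  n <- length(unique(s)) / 2          # subjects per group
  a <- 2; b <- 2; cc <- 3
  ss_group <- b * cc * n * sum((m_g - gm)^2)
  ss_subj <- b * cc * sum((m_s - m_g[subj_group[names(m_s)]])^2)
  ss_cond <- a * n * cc * sum((m_j - gm)^2)
  ss_cxg <- n * cc * sum((m_gj - outer(m_g, rep(1, b)) -
                            outer(rep(1, a), m_j) + gm)^2)
  err_cond <- 0
  for (ss_i in rownames(m_sj)) for (jj in colnames(m_sj)) {
    gg <- subj_group[ss_i]
    err_cond <- err_cond + (m_sj[ss_i, jj] - m_s[ss_i] - m_gj[gg, jj] + m_g[gg])^2
  }
  err_cond <- cc * err_cond
  ss_chan <- a * n * b * sum((m_k - gm)^2)
  ss_kxg <- n * b * sum((m_gk - outer(m_g, rep(1, cc)) -
                           outer(rep(1, a), m_k) + gm)^2)
  err_chan <- 0
  for (ss_i in rownames(m_sk)) for (kk in colnames(m_sk)) {
    gg <- subj_group[ss_i]
    err_chan <- err_chan + (m_sk[ss_i, kk] - m_s[ss_i] - m_gk[gg, kk] + m_g[gg])^2
  }
  err_chan <- b * err_chan
  ss_jk <- a * n * sum((m_jk - outer(m_j, rep(1, cc)) -
                          outer(rep(1, b), m_k) + gm)^2)
  ss_jkg <- 0
  for (gg in names(m_g)) for (jj in names(m_j)) for (kk in names(m_k)) {
    ss_jkg <- ss_jkg + (m_gjk[gg, jj, kk] - m_gj[gg, jj] - m_gk[gg, kk] -
                          m_jk[jj, kk] + m_g[gg] + m_j[jj] + m_k[kk] - gm)^2
  }
  ss_jkg <- n * ss_jkg
  err_jk <- 0
  for (r in seq_along(Y)) {
    gg <- g[r]
    err_jk <- err_jk + (Y[r] - m_sj[s[r], j[r]] - m_sk[s[r], k[r]] + m_s[s[r]] -
                          (m_gjk[gg, j[r], k[r]] - m_gj[gg, j[r]] -
                             m_gk[gg, k[r]] + m_g[gg]))^2
  }
  lapply(list(
    group = c(ss_group, 1, ss_subj, 2 * (n - 1)),
    condition = c(ss_cond, 1, err_cond, 2 * (n - 1)),
    `group:condition` = c(ss_cxg, 1, err_cond, 2 * (n - 1)),
    channel = c(ss_chan, 2, err_chan, 2 * 2 * (n - 1)),
    `group:channel` = c(ss_kxg, 2, err_chan, 2 * 2 * (n - 1)),
    `condition:channel` = c(ss_jk, 2, err_jk, 2 * 2 * (n - 1)),
    `group:condition:channel` = c(ss_jkg, 2, err_jk, 2 * 2 * (n - 1))), unname)
}
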