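test_that("event sequence has the designed target count and is seeded", {
  ev <- generate_event_sequence(session_config(), seed = 3)
  expect_identical(nrow(ev), 120L)
  expect_identical(sum(ev$condition == "target"), 40L)
  expect_identical(sum(ev$condition == "nontarget"), 80L)
  expect_true(!is.unsorted(ev$sample_index, strictly = TRUE))
  expect_identical(ev, generate_event_sequence(session_config(), seed = 3))
  expect_false(identical(ev$condition,
                         generate_event_sequence(session_config(), seed = 4)$condition))
})

test_that("inter-stimulus intervals are uniform on the configured range", {
  cfg <- session_config(n_stimuli = 10000)
  ev <- generate_event_sequence(cfg, seed = 5)
  isi <- diff(c(0, ev$onset_s))
  expect_equal(mean(isi), 5.0, tolerance = 0.05 / 5)
  expect_gte(min(isi), 3); expect_lte(max(isi), 7)
})

test_that("noiseless rendering places the exact template peak", {
  cfg <- session_config(n_stimuli = 1, p_target = 0.99)
  ev <- data.frame(sample_index = 2500L, onset_s = 5, condition = "target",
                   code = "S  2")
  pr <- noiseless_params(lat_target = 450, amp_target = 6)
  rec <- render_subject_recording(pr, ev, cfg, seed = 1)
  cz <- rec$data["Cz", ]
  expect_equal(max(cz), 6)
  # peak exactly 450 ms (225 samples) after onset
  expect_identical(which.max(cz) - 1L, 2500L + 225L)
  expect_identical(max(abs(rec$data["EOG", ])), 0)

  # zero amplitude and zero noise: all-silent EEG
  pr0 <- subject_erp_params(cell_matrix(450, 430), cell_matrix(0, 0),
                            noise = silent_noise())
  rec0 <- render_subject_recording(pr0, ev, cfg, seed = 1)
  expect_identical(max(abs(rec0$data)), 0)
})

test_that("blink generation is Poisson at the configured rate", {
  cfg <- session_config(n_stimuli = 2)
  # ~600 s session at 12 blinks/min
  ev <- data.frame(sample_index = c(1000L, 299000L), onset_s = c(2, 598),
                   condition = c("target", "nontarget"), code = c("S  2", "S  1"))
  nz <- noise_model(background_noise_sd = 0, alpha_power = 0,
                    blink_rate = 12, blink_amplitude_eog = 250, eog_noise_sd = 0)
  pr <- subject_erp_params(cell_matrix(450, 430), cell_matrix(0, 0), noise = nz)
  rec <- render_subject_recording(pr, ev, cfg, seed = 21)
  eog <- rec$data["EOG", ]
  # count threshold upcrossings at half blink amplitude
  up <- sum(diff(eog > 125) == 1)
  dur_min <- length(eog) / 500 / 60
  lambda <- 12 * dur_min
  expect_gt(up, lambda - 2 * sqrt(lambda) - 3)  # -3: rare overlapping blinks merge
  expect_lt(up, lambda + 2 * sqrt(lambda) + 1)
  # blinks propagate to EEG with the configured frontal gradient
  expect_gt(max(rec$data["Fz", ]), 0.3 * max(eog))
  expect_gt(max(rec$data["Fz", ]), max(rec$data["Pz", ]))
})

test_that("count-accuracy criterion implements the 10% rule", {
  expect_true(check_count_accuracy(40, 40))
  expect_true(check_count_accuracy(36, 40))   # 4/40 = 0.10, boundary passes
  expect_false(check_count_accuracy(35, 40))  # 5/40 = 0.125
  expect_true(check_count_accuracy(44, 40))   # symmetric bound
  expect_error(check_count_accuracy(-1, 40), "non-negative")
  expect_error(check_count_accuracy(40, 0), "positive")
})

test_that("uncoupled scores are independent of the latent factors", {
  sim <- simulate_cohort(group_model(n_subjects = c(HC = 10000)),
                         seed = 31, render = FALSE)
  z <- vapply(sim$params, function(p) p$z_latency, numeric(1))
  ds <- sim$cohort$DS_Forward
  expect_lt(abs(cor(ds, z)), 0.03)
})

test_that("generator group means converge to the calibration cells", {
  sim <- simulate_cohort(group_model(n_subjects = c(HC = 2000)),
                         seed = 17, render = FALSE)
  lat_fz <- vapply(sim$params, function(p) p$latency["target", "Fz"], numeric(1))
  expect_equal(mean(lat_fz), 413.789, tolerance = 2 / 413.789)
  amp_cz <- vapply(sim$params, function(p) p$amplitude["target", "Cz"], numeric(1))
  expect_equal(mean(amp_cz), 5.757, tolerance = 3 * 1.919 / sqrt(2000) / 5.757)
  # zero-sd marginal: every control scores the recognition ceiling
  expect_true(all(sim$cohort$OVMPT_TR == 15))
})

test_that("cohort simulation is deterministic and flags infeasible couplings", {
  m <- group_model(n_subjects = c(HC = 3, MCI = 3))
  s1 <- simulate_cohort(m, seed = 5, render = FALSE)
  s2 <- simulate_cohort(m, seed = 5, render = FALSE)
  expect_identical(s1, s2)
  expect_error(
    group_model(coupling = list(DS_Forward = c(latency = 0.9, amplitude = 0.9))),
    "infeasible coupling for DS_Forward")
})

test_that("coupling to the latent factors induces the configured sign", {
  m <- group_model(n_subjects = c(HC = 4000),
                   coupling = list(DS_Forward = c(latency = -0.6)))
  sim <- simulate_cohort(m, seed = 9, render = FALSE)
  z <- vapply(sim$params, function(p) p$z_latency, numeric(1))
  r <- cor(sim$cohort$DS_Forward, z)
  expect_lt(r, -0.5)  # rounding to integers attenuates slightly
})

test_that("reported counts follow the group-specific error model", {
  sim <- simulate_cohort(group_model(n_subjects = c(HC = 2000, MCI = 2000)),
                         seed = 23, render = FALSE)
  hc <- sim$cohort[sim$cohort$group == "HC", ]
  mci <- sim$cohort[sim$cohort$group == "MCI", ]
  expect_equal(mean(hc$reported_count), 40.55, tolerance = 0.003)
  expect_equal(mean(mci$reported_count), 39.75, tolerance = 0.004)
  expect_gt(sd(mci$reported_count), sd(hc$reported_count))
  expect_true(all(sim$cohort$true_target_count == 40))
})
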