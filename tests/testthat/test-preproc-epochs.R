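test_that("epoching yields 1000 ms windows with 200 ms pre-stimulus", {
  cfg <- session_config()
  ev <- generate_event_sequence(cfg, seed = 2)
  pr <- noiseless_params()
  rec <- render_subject_recording(pr, ev, cfg, seed = 3)
  ep <- epoch_data(rec)
  expect_identical(dim(ep$data), c(120L, 4L, 500L))
  expect_identical(range(ep$time), c(-200, 798))
  expect_identical(unique(diff(ep$time)), 2)
  expect_identical(ep$condition, ev$condition)
})

test_that("events without full window support are dropped with a warning", {
  data <- matrix(0, 1, 1000, dimnames = list("Fz", NULL))
  ev <- data.frame(sample_index = c(50L, 500L),
                   condition = c("target", "nontarget"), code = c("S  2", "S  1"))
  rec <- continuous_recording(data, 500, ev)
  expect_warning(ep <- epoch_data(rec), "dropped")
  expect_identical(dim(ep$data)[1], 1L)
  expect_identical(ep$condition, "nontarget")
})

test_that("an onset impulse lands at time zero of its epoch", {
  x <- numeric(2000); x[1001] <- 1      # 0-based sample 1000
  rec <- continuous_recording(matrix(x, 1, dimnames = list("Fz", NULL)), 500,
                              data.frame(sample_index = 1000L,
                                         condition = "target", code = "S  2"))
  ep <- epoch_data(rec)
  expect_identical(as.numeric(ep$data[1, 1, ep$time == 0]), 1)
  expect_identical(sum(ep$data), 1)
})

test_that("baseline correction zeroes the pre-stimulus mean", {
  traces <- list(rep(5, 500),                       # constant
                 c(numeric(100), sin(2 * pi * (1:400) / 50)),  # already zero baseline
                 seq(-200, 798, by = 2))            # ramp in ms units
  rec <- recording_from_epochs(traces)
  ep <- baseline_correct(epoch_data(rec))
  expect_lt(max(abs(ep$data[1, 1, ])), 1e-10)
  expect_equal(ep$data[2, 1, ], traces[[2]], tolerance = 1e-12)
  # ramp: subtract the closed-form mean of the 100 discrete baseline samples
  bl_mean <- mean(seq(-200, -2, by = 2))
  expect_equal(ep$data[3, 1, ], traces[[3]] - bl_mean, tolerance = 1e-12)
  bidx <- ep$time >= -200 & ep$time < 0
  expect_lt(max(abs(rowMeans(ep$data[, 1, bidx]))), 1e-10)
})

test_that("rejection implements the four-criterion truth table", {
  t_ms <- seq(-200, 798, by = 2)
  spike <- numeric(500); spike[300] <- 80          # (a) exceeds +/- 70
  flat <- numeric(500)                             # (d) zero activity
  sine10 <- 10 * sin(2 * pi * 10 * t_ms / 1000)    # passes everything
  step <- numeric(500); step[250:500] <- 120       # (b) 60 uV/ms step, also (a)
  drift <- seq(0, 60, length.out = 500)            # (c) 200 ms range ok? 60/1s
  rec <- recording_from_epochs(list(spike, flat, sine10, step, drift))
  ep <- baseline_correct(epoch_data(rec))
  ep <- reject_artifacts(ep)
  expect_identical(unname(ep$retained), c(FALSE, FALSE, TRUE, FALSE, TRUE))
  expect_gte(ep$rejection_counts[["max_abs"]], 2)
  expect_gte(ep$rejection_counts[["max_step"]], 1)
  expect_gte(ep$rejection_counts[["min_activity"]], 1)

  # 10 Hz 10 uV sinusoid survives every criterion by closed-form margins:
  # |x| = 10 <= 70; step 10*2*pi*10*0.002 = 1.26 uV per sample (0.63 uV/ms);
  # 200 ms range 20 <= 50; 100 ms range 20 >= 0.5
  expect_true(ep$retained[3])
})

test_that("a 55 uV step inside an epoch violates only the range criterion", {
  tr <- numeric(500); tr[200:500] <- 55   # within +/-70, step 27.5 uV/ms < 50
  rec <- recording_from_epochs(list(tr))
  ep <- reject_artifacts(baseline_correct(epoch_data(rec)))
  expect_false(ep$retained[1])
  expect_identical(unname(ep$rejection_counts[c("max_abs", "max_step", "max_range")]),
                   c(0L, 0L, 1L))
})

test_that("EOG activity does not trigger rejection", {
  n <- 4000
  data <- rbind(Fz = sin(2 * pi * 10 * (1:n) / 500) * 10,
                EOG = c(numeric(1400), 300 * exp(-((1:200) - 100)^2 / 500),
                        numeric(n - 1600)))
  rec <- continuous_recording(data, 500,
                              data.frame(sample_index = 1500L,
                                         condition = "target", code = "S  2"))
  ep <- reject_artifacts(baseline_correct(epoch_data(rec)))
  expect_true(all(ep$retained))
})

test_that("relaxing thresholds never rejects more epochs", {
  set.seed(20)
  traces <- replicate(40, rnorm(500, sd = runif(1, 5, 60)), simplify = FALSE)
  rec <- recording_from_epochs(traces)
  ep <- baseline_correct(epoch_data(rec))
  base_crit <- rejection_criteria()
  n0 <- sum(reject_artifacts(ep, base_crit)$retained)
  for (k in c(1.5, 3, 10)) {
    crit <- rejection_criteria(max_abs = 70 * k, max_step = 50 * k,
                               max_range = 50 * k, min_activity = 0.5 / k)
    expect_gte(sum(reject_artifacts(ep, crit)$retained), n0)
  }
})

test_that("equalization subsamples the larger condition reproducibly", {
  set.seed(21)
  traces <- lapply(1:113, function(i) rnorm(500, sd = 5))
  conds <- rep(c("target", "nontarget"), c(38, 75))
  rec <- recording_from_epochs(traces, conditions = conds)
  ep <- baseline_correct(epoch_data(rec))
  eq <- equalize_epoch_counts(ep, seed = 5)
  counts <- table(eq$condition[eq$retained])
  expect_identical(as.integer(counts[c("target", "nontarget")]), rep(38L, 2))
  # subset property: nothing new is retained
  expect_true(all(which(eq$retained) %in% which(ep$retained)))
  # determinism
  expect_identical(eq$retained, equalize_epoch_counts(ep, seed = 5)$retained)
  # equal counts: unchanged regardless of seed
  ep2 <- ep; ep2$retained[which(ep2$condition == "nontarget")[1:37]] <- FALSE
  expect_identical(equalize_epoch_counts(ep2, seed = 1)$retained,
                   equalize_epoch_counts(ep2, seed = 99)$retained)
  # empty condition errors
  ep3 <- ep; ep3$retained[ep3$condition == "target"] <- FALSE
  expect_error(equalize_epoch_counts(ep3, seed = 1), "zero retained")
})

test_that("minimum epoch check flags conditions below 20", {
  traces <- lapply(1:45, function(i) rnorm(500, sd = 5))
  conds <- rep(c("target", "nontarget"), c(20, 25))
  rec <- recording_from_epochs(traces, conditions = conds)
  ep <- baseline_correct(epoch_data(rec))
  expect_true(all(check_min_epochs(ep)))
  ep$retained[which(ep$condition == "target")[1]] <- FALSE
  chk <- check_min_epochs(ep)
  expect_false(chk[["target"]]); expect_true(chk[["nontarget"]])
  ep$retained[ep$condition == "nontarget"] <- FALSE
  expect_false(check_min_epochs(ep)[["nontarget"]])
})

test_that("peak latency of an injected template survives the filter chain", {
  cfg <- session_config()
  ev <- generate_event_sequence(cfg, seed = 40)
  pr <- noiseless_params(lat_target = 412, lat_nontarget = 500)
  rec <- render_subject_recording(pr, ev, cfg, seed = 41)
  filt <- filter_chain(rec)
  ep <- baseline_correct(epoch_data(filt))
  pk <- measure_peak(average_epochs(ep))
  expect_true(all(abs(pk$latency[pk$condition == "target"] - 412) <= 2))
  expect_true(all(abs(pk$latency[pk$condition == "nontarget"] - 500) <= 2))
})
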