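test_that("ANOVA matches the brute-force cell-means partition on toy designs", {
  set.seed(6)
  for (i in 1:5) {
    d <- simulate_measures(n_per_group = 2, subject_sd = 30, cell_sd = 20,
                           effects = list(interaction = runif(1, -40, 40)),
                           seed = 100 + i)
    ours <- mixed_anova_2x3x2(d)
    oracle <- anova_bruteforce(d)
    for (ef in names(oracle)) {
      row <- ours[ours$effect == ef, ]
      expect_equal(row$ss, oracle[[ef]][1], tolerance = 1e-8)
      expect_identical(row$df, oracle[[ef]][2])
      expect_equal(row$ss_error, oracle[[ef]][3], tolerance = 1e-8)
      expect_identical(row$df_error, oracle[[ef]][4])
      F_oracle <- (oracle[[ef]][1] / oracle[[ef]][2]) /
        (oracle[[ef]][3] / oracle[[ef]][4])
      expect_equal(row$F, F_oracle, tolerance = 1e-8)
    }
  }
})

test_that("ANOVA has the published degrees of freedom at n = 20 per group", {
  d <- simulate_measures(n_per_group = 20, seed = 7)
  a <- mixed_anova_2x3x2(d)
  ix <- a[a$effect == "group:condition", ]
  expect_identical(c(ix$df, ix$df_error), c(1, 38))
  expect_identical(a$df_error[a$effect == "group"], 38)
  expect_identical(a$df_error[a$effect == "group:channel"], 76)
})

test_that("F ratios are invariant under affine transforms of the measures", {
  d <- simulate_measures(n_per_group = 6, seed = 8,
                         effects = list(condition = 20, interaction = 15))
  a0 <- mixed_anova_2x3x2(d)
  d2 <- d; d2$value <- 3.7 * d$value + 120
  a2 <- mixed_anova_2x3x2(d2)
  expect_equal(a2$F, a0$F, tolerance = 1e-8)
  expect_equal(a2$p, a0$p, tolerance = 1e-8)
  expect_equal(a2$gg_epsilon, a0$gg_epsilon, tolerance = 1e-8)
})

test_that("degenerate and malformed designs raise errors", {
  d <- simulate_measures(n_per_group = 2, subject_sd = 0, cell_sd = 0, seed = 9)
  expect_error(mixed_anova_2x3x2(d), "degenerate")
  d2 <- simulate_measures(n_per_group = 3, seed = 10)
  expect_error(mixed_anova_2x3x2(d2[-1, ]), "exactly one value per cell")
  d3 <- d2; d3$group <- "HC"
  expect_error(mixed_anova_2x3x2(d3), "2 groups")
})

test_that("Greenhouse-Geisser epsilon lies in its theoretical range", {
  for (s in 1:5) {
    d <- simulate_measures(n_per_group = 10, seed = 20 + s)
    a <- mixed_anova_2x3x2(d)
    eps3 <- a$gg_epsilon[a$effect == "channel"]
    expect_gte(eps3, 0.5)   # lower bound 1/(k-1) for k = 3
    expect_lte(eps3, 1 + 1e-12)
    eps6 <- a$gg_epsilon[a$effect == "condition:channel"]
    expect_gte(eps6, 0.5); expect_lte(eps6, 1 + 1e-12)
  }
})

test_that("interaction p agrees with a group-label permutation oracle", {
  d <- simulate_measures(n_per_group = 10, subject_sd = 35, cell_sd = 25,
                         seed = 11)
  a <- mixed_anova_2x3x2(d)
  obs <- a$F[a$effect == "group:condition"]
  p_param <- a$p[a$effect == "group:condition"]
  subj <- unique(d$subject)
  set.seed(12)
  exceed <- replicate(1000, {
    perm <- setNames(sample(rep(c("HC", "MCI"), each = 10)), subj)
    d$group <- perm[d$subject]
    ap <- mixed_anova_2x3x2(d)
    ap$F[ap$effect == "group:condition"] >= obs
  })
  expect_equal(mean(exceed), p_param, tolerance = 0.03 / p_param)
})

test_that("post-hoc simple effects use the Bonferroni family of four", {
  d <- simulate_measures(n_per_group = 12, seed = 13,
                         effects = list(interaction = 60))
  ph <- simple_effects_posthoc(d, value = "value")
  expect_identical(nrow(ph), 4L)
  expect_equal(ph$p_bonferroni, pmin(1, ph$p * 4), tolerance = 1e-12)
  expect_true(any(grepl("target_vs_nontarget_in_MCI", ph$contrast)))
  expect_true(any(grepl("in_target$", ph$contrast)))
  # paired t on identical conditions is exactly zero
  d0 <- d
  d0$value <- ave(d0$value, d0$subject, d0$channel)  # same value both conditions
  ph0 <- simple_effects_posthoc(d0, value = "value")
  within_rows <- grepl("target_vs_nontarget", ph0$contrast)
  expect_true(all(ph0$t[within_rows] == 0))
  expect_true(all(ph0$p_bonferroni <= 1))
})

test_that("correlation battery flags a strong coupled score and honours families", {
  # measure-level cohort: peaks taken directly from the generator's cells
  m <- group_model(n_subjects = c(HC = 100, MCI = 100),
                   coupling = list(DS_Forward = c(latency = -0.6)))
  for (s in 1:3) {
    sim <- simulate_cohort(m, seed = 400 + s, render = FALSE)
    peaks <- do.call(rbind, lapply(names(sim$params), function(id) {
      p <- sim$params[[id]]
      do.call(rbind, lapply(c("target", "nontarget"), function(co)
        data.frame(subject_id = id, condition = co, channel = colnames(p$latency),
                   amplitude = p$amplitude[co, ], latency = p$latency[co, ],
                   stringsAsFactors = FALSE)))
    }))
    cb <- correlation_battery(peaks, sim$cohort)
    hit <- cb[cb$population == "MCI" & cb$condition == "target" &
                cb$measure == "latency" & cb$test == "DS_Forward", ]
    expect_true(all(hit$r < 0))
    expect_true(all(hit$significant))
  }
})

test_that("zero-variance scores yield undefined rows excluded from the FDR family", {
  sim <- simulate_cohort(group_model(n_subjects = c(HC = 20, MCI = 20)),
                         seed = 55, render = FALSE)
  peaks <- do.call(rbind, lapply(names(sim$params), function(id) {
    p <- sim$params[[id]]
    do.call(rbind, lapply(c("target", "nontarget"), function(co)
      data.frame(subject_id = id, condition = co, channel = colnames(p$latency),
                 amplitude = p$amplitude[co, ], latency = p$latency[co, ],
                 stringsAsFactors = FALSE)))
  }))
  cb <- correlation_battery(peaks, sim$cohort)
  # every healthy control scores the recognition ceiling -> undefined
  tr_hc <- cb[cb$population == "HC" & cb$test == "OVMPT_TR", ]
  expect_true(all(tr_hc$undefined))
  expect_true(all(is.na(tr_hc$p_fdr)))
  # defined rows keep p_fdr >= p and flags monotone in p within a family
  def <- cb[!cb$undefined, ]
  expect_true(all(def$p_fdr >= def$p - 1e-15))
  fam <- def[def$population == "whole" & def$condition == "target", ]
  ord <- order(fam$p)
  expect_true(!is.unsorted(fam$p_fdr[ord]))
})

test_that("correlation battery controls false discoveries under the null", {
  m <- group_model(n_subjects = c(HC = 20, MCI = 20))
  frac <- numeric(40)
  for (s in seq_along(frac)) {
    sim <- simulate_cohort(m, seed = 700 + s, render = FALSE)
    peaks <- do.call(rbind, lapply(names(sim$params), function(id) {
      p <- sim$params[[id]]
      do.call(rbind, lapply(c("target", "nontarget"), function(co)
        data.frame(subject_id = id, condition = co, channel = colnames(p$latency),
                   amplitude = p$amplitude[co, ], latency = p$latency[co, ],
                   stringsAsFactors = FALSE)))
    }))
    cb <- correlation_battery(peaks, sim$cohort)
    def <- cb[!cb$undefined, ]
    frac[s] <- mean(def$significant)
  }
  expect_lte(mean(frac), 0.05 + 0.02)
})

test_that("group comparison battery covers scores, counts and sex", {
  sim <- simulate_cohort(group_model(n_subjects = c(HC = 20, MCI = 20)),
                         seed = 66, render = FALSE)
  gc <- group_comparison_battery(sim$cohort)
  expect_true(all(c("age", "MMSE", "OVMPT_T", "reported_count", "sex") %in%
                    gc$variable))
  expect_identical(gc$test[gc$variable == "sex"], "chi_square")
  # 11 female / 9 male in both simulated groups: chi-square p = 1
  expect_equal(gc$p[gc$variable == "sex"], 1)
  # OVMPT_TR has zero variance in HC; pooled t still defined (MCI varies)
  expect_true(is.finite(gc$statistic[gc$variable == "OVMPT_TR"]))
})
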