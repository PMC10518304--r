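# Brain-behavior correlation battery and the demographic/neuropsychological
# group-comparison battery.

#' FDR-corrected brain-behavior correlation battery
#'
#' For each population (HC, MCI, whole sample), condition, channel, peak
#' measure (amplitude, latency) and neuropsychological score: Pearson r and
#' raw p with pairwise deletion, then Benjamini-Hochberg FDR within each
#' population x condition family. Zero-variance scores yield undefined rows
#' that are excluded from the FDR family but kept in the report.
#'
#' @param peaks data frame of peak measures (`subject_id`, `condition`,
#'   `channel`, `amplitude`, `latency`), one row per subject x condition x
#'   channel.
#' @param cohort a [cohort_table()].
#' @param tests score columns to correlate (default [score_columns()] minus
#'   the depression screen).
#' @param q FDR criterion.
#' @return data frame with columns `population`, `condition`, `channel`,
#'   `measure`, `test`, `r`, `n`, `p`, `p_fdr`, `significant`, `undefined`.
#' @export
correlation_battery <- function(peaks, cohort,
                                tests = setdiff(score_columns(cohort), "GDS"),
                                q = 0.05) {
  stop_if_not(all(peaks$subject_id %in% cohort$id),
              "peak table contains subjects absent from the cohort table")
  pops <- list(HC = cohort$id[cohort$group == "HC"],
               MCI = cohort$id[cohort$group == "MCI"],
               whole = cohort$id)
  out <- list()
  for (pop in names(pops)) {
    ids <- pops[[pop]]
    for (co in unique(peaks$condition)) {
      fam <- list()
      for (ch in unique(peaks$channel)) {
        sel <- peaks$condition == co & peaks$channel == ch &
          peaks$subject_id %in% ids
        pk <- peaks[sel, ]
        pk <- pk[match(intersect(ids, pk$subject_id), pk$subject_id), ]
        sc <- cohort[match(pk$subject_id, cohort$id), ]
        for (ms in c("amplitude", "latency")) {
          for (te in tests) {
            r <- pearson_correlation(pk[[ms]], sc[[te]])
            fam[[length(fam) + 1]] <- data.frame(
              population = pop, condition = co, channel = ch, measure = ms,
              test = te, r = r$r, n = r$n, p = r$p, undefined = r$undefined,
              stringsAsFactors = FALSE)
          }
        }
      }
      fam <- do.call(rbind, fam)
      adj <- bh_fdr_adjust(fam$p, q = q)
      fam$p_fdr <- adj$adjusted
      fam$significant <- adj$significant
      out[[length(out) + 1]] <- fam
    }
  }
  res <- do.call(rbind, out)
  res[, c("population", "condition", "channel", "measure", "test",
          "r", "n", "p", "p_fdr", "significant", "undefined")]
}

#' Group comparisons of demographics and scores
#'
#' Pooled independent t-tests (HC vs MCI) on age, education, every score
#' column and the behavioral count report, plus the chi-square test on the
#' sex table.
#'
#' @param cohort a [cohort_table()].
#' @return data frame with columns `variable`, `test`, `statistic`, `df`, `p`.
#' @export
group_comparison_battery <- function(cohort) {
  hc <- cohort[cohort$group == "HC", ]
  mci <- cohort[cohort$group == "MCI", ]
  vars <- intersect(c("age", "education", score_columns(cohort), "reported_count"),
                    names(cohort))
  rows <- lapply(vars, function(v) {
    tr <- tryCatch(ttest_independent(hc[[v]], mci[[v]]), error = function(e) NULL)
    if (is.null(tr)) {
      data.frame(variable = v, test = "t", statistic = NA_real_, df = NA_real_,
                 p = NA_real_, stringsAsFactors = FALSE)
    } else {
      data.frame(variable = v, test = "t", statistic = tr$t, df = tr$df,
                 p = tr$p, stringsAsFactors = FALSE)
    }
  })
  if ("sex" %in% names(cohort)) {
    tab <- table(cohort$group, cohort$sex)
    if (all(dim(tab) == 2)) {
      cs <- chi_square_2x2(matrix(tab, 2, 2))
      rows[[length(rows) + 1]] <- data.frame(
        variable = "sex", test = "chi_square", statistic = cs$chi2,
        df = cs$df, p = cs$p, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
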