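# Mixed-design 2 (group) x 2 (condition) x 3 (anterior-posterior channel)
# repeated-measures ANOVA with univariate error strata, Greenhouse-Geisser
# epsilon for the multi-level within factors, and the four simple-effect
# post-hoc tests with Bonferroni correction.

gg_epsilon <- function(scores, group) {
  # scores: subjects x p matrix of repeated measures for one within effect;
  # pooled within-group covariance; epsilon on the orthonormal contrasts.
  p <- ncol(scores)
  cent <- scores
  for (g in unique(group)) {
    sel <- group == g
    cent[sel, ] <- sweep(scores[sel, , drop = FALSE], 2,
                         colMeans(scores[sel, , drop = FALSE]))
  }
  S <- crossprod(cent) / (nrow(scores) - length(unique(group)))
  C <- stats::contr.helmert(p)
  C <- t(qr.Q(qr(C)))                   # (p-1) x p orthonormal contrasts
  M <- C %*% S %*% t(C)
  d <- nrow(M)
  sum(diag(M))^2 / (d * sum(M^2))
}

#' Mixed-design 2x3x2 repeated-measures ANOVA
#'
#' Univariate decomposition for a design with one between-subject factor
#' (group) and two within-subject factors (condition: target/non-target;
#' channel: Fz/Cz/Pz, the anterior-posterior factor). The between stratum
#' tests group against subjects-within-group; each within effect and its
#' group interaction is tested against the corresponding
#' effect-by-subject-within-group error. Greenhouse-Geisser epsilon is
#' reported for the multi-level within effects; headline p-values are the
#' uncorrected (integer-df) ones.
#'
#' @param data long data frame with columns `subject`, `group` (2 levels),
#'   `condition` (2 levels), `channel` (3 levels), and the dependent value.
#' @param value name of the dependent-value column.
#' @return data frame with columns `effect`, `ss`, `df`, `ss_error`,
#'   `df_error`, `F`, `p`, `pes` (partial eta squared), `gg_epsilon`.
#' @export
mixed_anova_2x3x2 <- function(data, value = "value") {
  need <- c("subject", "group", "condition", "channel", value)
  stop_if_not(all(need %in% names(data)), "missing columns: %s",
              paste(setdiff(need, names(data)), collapse = ", "))
  d <- data.frame(subject = factor(data$subject), group = factor(data$group),
                  condition = factor(data$condition),
                  channel = factor(data$channel), y = data[[value]])
  stop_if_not(nlevels(d$group) == 2, "need exactly 2 groups")
  stop_if_not(nlevels(d$condition) == 2 && nlevels(d$channel) == 3,
              "need 2 conditions and 3 channels")
  cells <- table(d$subject, d$condition, d$channel)
  stop_if_not(all(cells == 1),
              "every subject must contribute exactly one value per cell (no imputation)")
  stop_if_not(!anyNA(d$y), "missing values in the dependent variable")

  fit <- aov(y ~ group * condition * channel + Error(subject / (condition * channel)),
             data = d)
  sm <- summary(fit)

  grab <- function(stratum) {
    tab <- sm[[stratum]][[1]]
    rn <- trimws(rownames(tab))
    data.frame(effect = rn, ss = tab[["Sum Sq"]], df = tab[["Df"]],
               F = if ("F value" %in% names(tab)) tab[["F value"]] else NA,
               p = if ("Pr(>F)" %in% names(tab)) tab[["Pr(>F)"]] else NA,
               stringsAsFactors = FALSE)
  }
  strata <- list(between = grab("Error: subject"),
                 condition = grab("Error: subject:condition"),
                 channel = grab("Error: subject:channel"),
                 cxc = grab("Error: subject:condition:channel"))

  rows <- list()
  for (st in strata) {
    err <- st[st$effect == "Residuals", ]
    stop_if_not(nrow(err) == 1 && err$ss > 1e-10,
                "degenerate design: zero error sum of squares in a stratum")
    for (i in which(st$effect != "Residuals")) {
      rows[[length(rows) + 1]] <- data.frame(
        effect = st$effect[i], ss = st$ss[i], df = st$df[i],
        ss_error = err$ss, df_error = err$df,
        F = st$F[i], p = st$p[i],
        pes = st$ss[i] / (st$ss[i] + err$ss),
        gg_epsilon = NA_real_, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)

  # epsilon for the 3-level factor and the 2x3 interaction cells
  wide_ch <- with(d, tapply(y, list(subject, channel), mean))
  subj_group <- d$group[match(rownames(wide_ch), d$subject)]
  eps_ch <- gg_epsilon(wide_ch, subj_group)
  cellm <- with(d, tapply(y, list(subject, interaction(condition, channel)), mean))
  eps_cxc <- gg_epsilon(cellm, subj_group)
  out$gg_epsilon[out$effect %in% c("channel", "group:channel")] <- eps_ch
  out$gg_epsilon[out$effect %in% c("condition:channel", "group:condition:channel")] <- eps_cxc
  rownames(out) <- NULL
  out
}

#' Simple-effect post-hoc tests for the condition-by-group interaction
#'
#' The four simple effects on electrode-averaged values: paired t
#' (target vs non-target) within each group and pooled independent t
#' (HC vs MCI) within each condition, Bonferroni-adjusted for the family of
#' four (adjusted p capped at 1).
#'
#' @param data long data frame as for [mixed_anova_2x3x2()].
#' @param value dependent-value column name.
#' @param family_size Bonferroni multiplier.
#' @return data frame with columns `contrast`, `t`, `df`, `p`, `p_bonferroni`.
#' @export
simple_effects_posthoc <- function(data, value = "value", family_size = 4) {
  d <- data.frame(subject = as.character(data$subject), group = data$group,
                  condition = data$condition, y = data[[value]])
  # electrode-averaged value per subject x condition
  avg <- stats::aggregate(y ~ subject + group + condition, d, mean)
  wide <- merge(avg[avg$condition == "target", c("subject", "group", "y")],
                avg[avg$condition == "nontarget", c("subject", "y")],
                by = "subject", suffixes = c("_target", "_nontarget"))
  rows <- list()
  add <- function(contrast, tr) {
    rows[[length(rows) + 1]] <<- data.frame(
      contrast = contrast, t = tr$t, df = tr$df, p = tr$p,
      p_bonferroni = min(1, tr$p * family_size), stringsAsFactors = FALSE)
  }
  for (g in unique(wide$group)) {
    sel <- wide$group == g
    add(sprintf("target_vs_nontarget_in_%s", g),
        ttest_paired(wide$y_target[sel], wide$y_nontarget[sel]))
  }
  groups <- unique(wide$group)
  for (co in c("target", "nontarget")) {
    col <- paste0("y_", co)
    add(sprintf("%s_vs_%s_in_%s", groups[1], groups[2], co),
        ttest_independent(wide[[col]][wide$group == groups[1]],
                          wide[[col]][wide$group == groups[2]]))
  }
  do.call(rbind, rows)
}
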