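# Published group-level summary statistics from the MCI-vs-control visual
# oddball study that the generator is calibrated to. These printed summary
# tables are inputs to the package: they seed the simulator defaults and the
# summary-statistic group comparisons.

#' Reference P300 peak summaries (group calibration)
#'
#' Group-level mean and standard deviation of P300 peak amplitude (microvolts)
#' and peak latency (ms) at Fz/Cz/Pz for target and non-target stimuli, in
#' 20 healthy controls (HC) and 20 MCI participants.
#'
#' @return data frame with columns `group`, `condition`, `channel`,
#'   `measure`, `mean`, `sd`.
#' @export
p300_reference <- function() {
  g <- function(group, condition, channel, measure, mean, sd)
    data.frame(group = group, condition = condition, channel = channel,
               measure = measure, mean = mean, sd = sd,
               stringsAsFactors = FALSE)
  rbind(
    g("HC",  "target",    "Fz", "amplitude",   5.854,  2.121),
    g("MCI", "target",    "Fz", "amplitude",   6.092,  3.005),
    g("HC",  "target",    "Fz", "latency",   413.789, 29.081),
    g("MCI", "target",    "Fz", "latency",   443.619, 56.465),
    g("HC",  "target",    "Cz", "amplitude",   5.757,  1.919),
    g("MCI", "target",    "Cz", "amplitude",   5.386,  2.804),
    g("HC",  "target",    "Cz", "latency",   419.053, 30.312),
    g("MCI", "target",    "Cz", "latency",   455.048, 64.005),
    g("HC",  "target",    "Pz", "amplitude",   5.438,  1.906),
    g("MCI", "target",    "Pz", "amplitude",   4.745,  2.486),
    g("HC",  "target",    "Pz", "latency",   419.053, 43.703),
    g("MCI", "target",    "Pz", "latency",   452.381, 60.417),
    g("HC",  "nontarget", "Fz", "amplitude",   4.503,  1.722),
    g("MCI", "nontarget", "Fz", "amplitude",   4.581,  2.339),
    g("HC",  "nontarget", "Fz", "latency",   443.474, 57.418),
    g("MCI", "nontarget", "Fz", "latency",   434.381, 59.979),
    g("HC",  "nontarget", "Cz", "amplitude",   4.811,  1.600),
    g("MCI", "nontarget", "Cz", "amplitude",   4.086,  1.882),
    g("HC",  "nontarget", "Cz", "latency",   449.053, 72.631),
    g("MCI", "nontarget", "Cz", "latency",   422.762, 68.210),
    g("HC",  "nontarget", "Pz", "amplitude",   4.020,  1.478),
    g("MCI", "nontarget", "Pz", "amplitude",   3.602,  1.776),
    g("HC",  "nontarget", "Pz", "latency",   437.684, 63.394),
    g("MCI", "nontarget", "Pz", "latency",   410.762, 77.801)
  )
}

#' Reference demographic and neuropsychological summaries
#'
#' Per-group means and standard deviations of demographics and the
#' neuropsychological test scores (MMSE, geriatric depression scale GDS,
#' Oktem verbal memory processes test total/immediate/free/total-recognition,
#' WMS-R digit span forward/backward, Stroop interference time, semantic
#' fluency animal naming, 15-item Boston naming test), n = 20 per group.
#'
#' @return data frame with columns `variable`, `hc_mean`, `hc_sd`,
#'   `mci_mean`, `mci_sd`, `integer` (whether the score is integer-valued),
#'   `lower`, `upper` (hard score bounds, NA when unbounded).
#' @export
neuropsych_reference <- function() {
  r <- function(variable, hm, hs, mm, ms, int = FALSE, lo = NA, hi = NA)
    data.frame(variable = variable, hc_mean = hm, hc_sd = hs,
               mci_mean = mm, mci_sd = ms, integer = int,
               lower = lo, upper = hi, stringsAsFactors = FALSE)
  rbind(
    r("age",         71.00,  5.96, 70.65,  7.08, FALSE, 0, NA),
    r("education",   10.30,  4.11, 10.20,  4.99, FALSE, 0, NA),
    r("MMSE",        29.31,  0.82, 25.85,  3.30, TRUE,  0, 30),
    r("GDS",          6.00,  3.71,  8.20,  5.31, TRUE,  0, 30),
    r("OVMPT_T",    109.25, 13.92, 68.65, 18.75, TRUE,  0, 150),
    r("OVMPT_IR",     4.50,  1.43,  3.65,  1.66, TRUE,  0, 15),
    r("OVMPT_FR",    12.65,  1.35,  5.50,  3.62, TRUE,  0, 15),
    r("OVMPT_TR",    15.00,  0.00, 13.35,  1.46, TRUE,  0, 15),
    r("DS_Forward",   5.10,  0.91,  4.95,  0.97, TRUE,  0, NA),
    r("DS_Backward",  3.90,  0.97,  3.37,  0.68, TRUE,  0, NA),
    r("Stroop_Int",  47.75, 21.43, 68.06, 38.71, FALSE, 0, NA),
    r("Animal",      22.55,  4.03, 16.55,  2.35, TRUE,  0, NA),
    r("BNT_15",      14.92,  0.28, 13.94,  1.70, FALSE, 0, 15)
  )
}

#' Reference behavioral target-count summaries
#'
#' Reported mental counts of the 40 target stimuli (mean +/- sd per group).
#' @return data frame with columns `group`, `mean`, `sd`, `true_targets`.
#' @export
behavior_reference <- function() {
  data.frame(group = c("HC", "MCI"), mean = c(40.55, 39.75),
             sd = c(1.61, 2.29), true_targets = 40L,
             stringsAsFactors = FALSE)
}

#' Reference sex contingency table
#' @return 2x2 integer matrix (rows: groups, columns F/M).
#' @export
sex_reference <- function() {
  matrix(c(11L, 9L, 11L, 9L), nrow = 2, byrow = TRUE,
         dimnames = list(c("HC", "MCI"), c("F", "M")))
}
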