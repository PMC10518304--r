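# Per-subject cohort table: group membership, demographics, neuropsychological
# scores, and behavioral target-count report. Scores may be missing (NA).

COHORT_BASE_COLS <- c("id", "group", "age", "education", "sex",
                      "reported_count", "true_target_count")

#' Validate and class a cohort table
#'
#' @param df data frame with at least columns `id` and `group`; `group`
#'   values must be `"HC"` or `"MCI"`. Any numeric columns beyond the base
#'   demographic/behavioral set are treated as neuropsychological scores.
#' @return the data frame with class `cohort_table`.
#' @export
cohort_table <- function(df) {
  stop_if_not(is.data.frame(df), "cohort table must be a data frame")
  stop_if_not(all(c("id", "group") %in% names(df)),
              "cohort table requires columns `id` and `group`")
  stop_if_not(!anyDuplicated(df$id), "duplicate subject ids in cohort table")
  bad <- setdiff(unique(df$group), c("HC", "MCI"))
  stop_if_not(length(bad) == 0, "group values outside {HC, MCI}: %s",
              paste(bad, collapse = ", "))
  if (!is.null(df$reported_count)) {
    stop_if_not(all(is.na(df$reported_count) | df$reported_count >= 0),
                "reported_count must be >= 0")
  }
  class(df) <- c("cohort_table", "data.frame")
  df
}

#' Score columns of a cohort table
#' @param cohort a [cohort_table()].
#' @return character vector of neuropsychological score column names.
#' @export
score_columns <- function(cohort) {
  cand <- setdiff(names(cohort), COHORT_BASE_COLS)
  cand[vapply(cohort[cand], is.numeric, logical(1))]
}

#' Read / write a cohort table as TSV
#'
#' Tab-separated with a header row; empty cells are missing values.
#' @param path file path.
#' @return [read_cohort_table()] returns a [cohort_table()].
#' @export
read_cohort_table <- function(path) {
  stop_if_not(file.exists(path), "cohort table not found: %s", path)
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   check.names = FALSE, na.strings = c("NA", ""))
  df$id <- as.character(df$id)
  cohort_table(df)
}

#' @rdname read_cohort_table
#' @param cohort a [cohort_table()].
#' @export
write_cohort_table <- function(cohort, path) {
  stop_if_not(inherits(cohort, "cohort_table"), "not a cohort_table")
  write.table(cohort, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}
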