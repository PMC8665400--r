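#' Cohort tables
#'
#' A cohort table holds one row per participant: identifier, trial arm
#' (`"experimental"` or `"control"`), age in years, sex, medication and
#' psychological-treatment flags, and pre/post scores of the primary outcome
#' (CPT-III commission T scores, where higher means worse inhibitory control).
#' Additional numeric columns are carried through untouched as secondary
#' outcomes.
#'
#' @param data A data.frame with at least the columns `participant_id`, `arm`,
#'   `age`, `sex`, `medicated`, `psych_treatment`, `cpt_commission_pre`,
#'   `cpt_commission_post`.
#' @param age_range Permitted age range in years (inclusive).
#' @return A validated `cohort_table` (a data.frame subclass).
#' @export
cohort_table <- function(data, age_range = c(8, 11)) {
  required <- c("participant_id", "arm", "age", "sex", "medicated",
                "psych_treatment", "cpt_commission_pre", "cpt_commission_post")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols))
    stopf("cohort table is missing required columns: %s",
          paste(missing_cols, collapse = ", "))
  if (nrow(data) == 0L) stopf("no participants in cohort table")
  data$participant_id <- as.character(data$participant_id)
  dup <- unique(data$participant_id[duplicated(data$participant_id)])
  if (length(dup))
    stopf("duplicated participant id(s): %s", paste(dup, collapse = ", "))
  if (!all(data$arm %in% c("experimental", "control")))
    stopf("unknown arm label(s): %s",
          paste(unique(setdiff(data$arm, c("experimental", "control"))), collapse = ", "))
  if (!all(table(factor(data$arm, c("experimental", "control"))) > 0L))
    stopf("both arms must be nonempty")
  for (col in c("age", "cpt_commission_pre", "cpt_commission_post")) {
    if (!is.numeric(data[[col]]) || anyNA(data[[col]]) || any(!is.finite(data[[col]])))
      stopf("column '%s' must be finite numeric", col)
  }
  if (any(data$age < age_range[1] | data$age > age_range[2]))
    stopf("ages outside the configured range [%g, %g]", age_range[1], age_range[2])
  data$medicated <- as.logical(data$medicated)
  data$psych_treatment <- as.logical(data$psych_treatment)
  class(data) <- unique(c("cohort_table", class(data)))
  data
}

#' Read a cohort table from delimited text
#'
#' Reads the tab-separated `cohort.tsv` layout (header row; logical flags as
#' TRUE/FALSE) and validates it.
#'
#' @param path Path to the file.
#' @param age_range Permitted age range in years.
#' @return A `cohort_table`.
#' @export
load_cohort_table <- function(path, age_range = c(8, 11)) {
  if (!file.exists(path)) stopf("cohort file not found: %s", path)
  data <- tryCatch(
    utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                      check.names = FALSE),
    error = function(e) stopf("no participants: could not read '%s' (%s)",
                              path, conditionMessage(e)))
  if (nrow(data) == 0L) stopf("no participants in '%s'", path)
  cohort_table(data, age_range = age_range)
}

#' Write a cohort table
#'
#' @param cohort A `cohort_table`.
#' @param path Destination file (tab-separated, header row).
#' @return `path`, invisibly.
#' @export
write_cohort_table <- function(cohort, path) {
  utils::write.table(as.data.frame(cohort), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Per-participant behavioural post/pre ratio
#'
#' The CPT commission ratio: post-intervention commission score divided by the
#' pre-intervention score. Values below 1 indicate improved inhibitory control.
#'
#' @param cohort A `cohort_table`.
#' @return Named numeric vector (names are participant ids, in cohort order).
#' @export
compute_cpt_ratio <- function(cohort) {
  if (any(cohort$cpt_commission_pre <= 0))
    stopf("pre-intervention scores must be positive to form a ratio")
  stats::setNames(cohort$cpt_commission_post / cohort$cpt_commission_pre,
                  cohort$participant_id)
}
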