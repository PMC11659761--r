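#' Per-sample metadata table
#'
#' Validates a data frame of per-sample metadata: donor age in years, sex,
#' tissue label, condition (healthy / case / control), an optional
#' actigraphy covariate in counts/day for intervention cohorts, and a
#' cohort label.
#'
#' @param df Data frame with at least a \code{sample_id} column. Missing
#'   optional columns are filled with sensible defaults (\code{sex}
#'   "unknown", \code{condition} "healthy", \code{activity} NA).
#' @return A \code{data.frame} of class \code{SampleTable} with columns
#'   sample_id, age, sex, tissue, condition, activity, cohort.
#' @export
sample_table <- function(df) {
  if (!"sample_id" %in% names(df))
    stop("sample table requires a `sample_id` column", call. = FALSE)
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id values in sample table", call. = FALSE)
  if (is.null(df$age)) df$age <- NA_real_
  df$age <- as.numeric(df$age)
  if (any(!is.na(df$age) & df$age <= 0))
    stop("ages must be positive where present", call. = FALSE)
  if (is.null(df$sex)) df$sex <- "unknown"
  df$sex <- as.character(df$sex)
  bad_sex <- !df$sex %in% c("male", "female", "unknown")
  if (any(bad_sex)) df$sex[bad_sex] <- "unknown"
  if (is.null(df$tissue)) df$tissue <- NA_character_
  df$tissue <- as.character(df$tissue)
  if (is.null(df$condition)) df$condition <- "healthy"
  df$condition <- as.character(df$condition)
  if (!all(df$condition %in% c("healthy", "case", "control")))
    stop("condition must be one of healthy/case/control", call. = FALSE)
  if (is.null(df$activity)) df$activity <- NA_real_
  df$activity <- as.numeric(df$activity)
  if (any(!is.na(df$activity) & df$activity < 0))
    stop("activity (counts/day) must be non-negative", call. = FALSE)
  if (is.null(df$cohort)) df$cohort <- NA_character_
  df$cohort <- as.character(df$cohort)
  cols <- c("sample_id", "age", "sex", "tissue", "condition", "activity",
            "cohort")
  out <- df[, c(cols, setdiff(names(df), cols)), drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("SampleTable", "data.frame")
  out
}

#' Read a sample metadata table from TSV
#'
#' Rows whose age cannot be parsed as a number are dropped and the dropped
#' count is reported via \code{message()}, never silently.
#'
#' @param path Tab-delimited file with named columns; \code{sample_id}
#'   required, \code{age} parseable as a number where present.
#' @return A \code{SampleTable}.
#' @export
read_sample_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!"sample_id" %in% names(df))
    stop("sample table format error: missing `sample_id` column in ", path,
         call. = FALSE)
  if ("age" %in% names(df)) {
    parsed <- suppressWarnings(as.numeric(df$age))
    bad <- is.na(parsed) & !is.na(df$age) & df$age != "" & df$age != "NA"
    if (any(bad)) {
      message(sprintf("read_sample_table: dropped %d row(s) with unparseable age",
                      sum(bad)))
      df <- df[!bad, , drop = FALSE]
      parsed <- parsed[!bad]
    }
    df$age <- parsed
  }
  sample_table(df)
}

#' Write a sample metadata table to TSV
#' @param samples A \code{SampleTable}.
#' @param path Output file path.
#' @export
write_sample_table <- function(samples, path) {
  utils::write.table(as.data.frame(samples), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
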