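COHORT_REQUIRED <- c("id", "group", "sex", "site", "age", "fsiq")

#' Read a cohort table
#'
#' Reads the per-subject TSV driving the analysis. Required columns:
#' `id`, `group` (ASD/TD), `sex` (male/female), `site`, `age`, `fsiq`.
#' Any further numeric columns (e.g. `aq`, `bdi`, `bai`) are kept as
#' clinical scores; columns named `path_*` are kept as input paths.
#'
#' @param path TSV file with a header row.
#' @return a `data.frame` of class `cohort_table`.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path))
    stop_fmt("io_error", "cohort file does not exist: %s", path)
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   check.names = FALSE)
  validate_cohort(df, path = path)
}

#' Validate (and type) a cohort table
#'
#' @param df data.frame with the cohort columns.
#' @param path optional source path used in error messages.
#' @param require_two_levels require >= 2 represented levels for group, sex
#'   and site (needed for the group-by-sex model to be estimable).
#' @return the typed `cohort_table`.
#' @export
validate_cohort <- function(df, path = "<in-memory>",
                            require_two_levels = TRUE) {
  missing_cols <- setdiff(COHORT_REQUIRED, names(df))
  if (length(missing_cols))
    stop_fmt("schema_error", "cohort %s is missing column(s): %s",
             path, paste(missing_cols, collapse = ", "))
  for (col in c("age", "fsiq")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]) & df[[col]] != "")
    if (length(bad))
      stop_fmt("schema_error",
               "cohort %s: unparseable %s at line(s) %s",
               path, col, paste(bad + 1L, collapse = ", "))
    df[[col]] <- v
  }
  if (anyNA(df$age) || anyNA(df$fsiq) || anyNA(df$group) ||
      anyNA(df$sex) || anyNA(df$site))
    stop_fmt("schema_error",
             "cohort %s has missing values in model covariates", path)
  df$group <- as.character(df$group)
  df$sex <- as.character(df$sex)
  df$site <- as.character(df$site)
  if (require_two_levels) {
    for (col in c("group", "sex", "site")) {
      if (length(unique(df[[col]])) < 2L)
        stop_fmt("design_error",
                 "cohort %s: '%s' has a single level; group-by-sex model inestimable",
                 path, col)
    }
  }
  class(df) <- c("cohort_table", "data.frame")
  df
}

#' Write a cohort table as TSV
#'
#' @param cohort a `cohort_table` (or plain data.frame).
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  write.table(as.data.frame(cohort), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

# numeric clinical-score columns = numeric columns beyond the model ones
clinical_score_names <- function(cohort) {
  cand <- setdiff(names(cohort), c(COHORT_REQUIRED,
                                   grep("^path_", names(cohort),
                                        value = TRUE)))
  cand[vapply(cohort[cand], is.numeric, logical(1))]
}
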