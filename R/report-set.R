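#' Spontaneous-report set
#'
#' A `report_set` is the in-memory form of a FAERS-style spontaneous-report
#' database: one demographic row per report plus two long tables holding the
#' verbatim drug mentions and the reaction Preferred Terms (PTs) of each
#' report. It is the common currency of the pipeline — readers produce it,
#' [deduplicate()] cleans it, and the screening and overview functions
#' consume it.
#'
#' @param demo Tibble with columns `report_id`, `case_id`, `version`, `sex`,
#'   `age_value`, `age_unit`, `country`. `sex` must be one of
#'   `"male"`, `"female"`, `"unknown"`; `age_unit` one of `"years"`,
#'   `"months"`, `"days"` or `NA`.
#' @param drugs Tibble with columns `report_id`, `drug_name` (verbatim
#'   strings as reported). Every report must have at least one mention.
#' @param reactions Tibble with columns `report_id`, `pt` (MedDRA Preferred
#'   Term strings). A report may have none.
#' @param provenance Free-text label recording where the data came from.
#'
#' @details Invariants enforced at construction: `report_id` unique;
#'   `(case_id, version)` unique; `version >= 1`; every report has at least
#'   one non-empty drug mention; drug and reaction rows only reference known
#'   report ids. An `age_years` column is derived from `age_value`/`age_unit`
#'   (months / 12, days / 365.25); a present value with a missing unit is
#'   taken as years, with a warning.
#'
#' @return An object of class `report_set`: a list with elements `demo`
#'   (including the derived `age_years`), `drugs`, `reactions`, `provenance`.
#' @export
report_set <- function(demo, drugs, reactions, provenance = "unspecified") {
  demo <- tibble::as_tibble(demo)
  drugs <- tibble::as_tibble(drugs)
  reactions <- tibble::as_tibble(reactions)

  check_columns(demo, c("report_id", "case_id", "version", "sex",
                        "age_value", "age_unit", "country"), "demo")
  check_columns(drugs, c("report_id", "drug_name"), "drug")
  check_columns(reactions, c("report_id", "pt"), "reac")

  demo$report_id <- as.character(demo$report_id)
  demo$case_id <- as.character(demo$case_id)
  demo$version <- as.integer(demo$version)
  drugs$report_id <- as.character(drugs$report_id)
  drugs$drug_name <- as.character(drugs$drug_name)
  reactions$report_id <- as.character(reactions$report_id)
  reactions$pt <- as.character(reactions$pt)

  if (anyDuplicated(demo$report_id)) {
    dup <- unique(demo$report_id[duplicated(demo$report_id)])
    stop("duplicate report_id in demo table: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  # duplicate (case_id, version) pairs are tolerated here — real spontaneous
  # databases contain them — and resolved by deduplicate()'s report_id tie
  # rule
  if (any(!is.na(demo$version) & demo$version < 1L)) {
    stop("version must be >= 1", call. = FALSE)
  }
  bad_sex <- setdiff(unique(demo$sex), c("male", "female", "unknown", NA))
  if (length(bad_sex) > 0) {
    stop("invalid sex value(s): ", paste(bad_sex, collapse = ", "),
         call. = FALSE)
  }
  bad_unit <- setdiff(unique(demo$age_unit), c("years", "months", "days", NA))
  if (length(bad_unit) > 0) {
    stop("invalid age_unit value(s): ", paste(bad_unit, collapse = ", "),
         call. = FALSE)
  }

  orphan_drug <- setdiff(drugs$report_id, demo$report_id)
  if (length(orphan_drug) > 0) {
    stop("drug table references unknown report_id(s): ",
         paste(sort(orphan_drug), collapse = ", "), call. = FALSE)
  }
  orphan_reac <- setdiff(reactions$report_id, demo$report_id)
  if (length(orphan_reac) > 0) {
    stop("reac table references unknown report_id(s): ",
         paste(sort(orphan_reac), collapse = ", "), call. = FALSE)
  }
  if (any(is.na(drugs$drug_name) | trimws(drugs$drug_name) == "")) {
    stop("drug table contains empty drug_name entries", call. = FALSE)
  }
  no_drug <- setdiff(demo$report_id, drugs$report_id)
  if (length(no_drug) > 0) {
    stop("report(s) with zero drug mentions: ",
         paste(sort(no_drug), collapse = ", "), call. = FALSE)
  }

  demo$age_years <- age_to_years(demo$age_value, demo$age_unit)

  structure(
    list(demo = demo, drugs = drugs, reactions = reactions,
         provenance = provenance),
    class = "report_set"
  )
}

#' @export
print.report_set <- function(x, ...) {
  cat("<report_set> ", nrow(x$demo), " reports (",
      dplyr::n_distinct(x$demo$case_id), " cases), ",
      nrow(x$drugs), " drug mentions, ",
      nrow(x$reactions), " reaction PTs\n", sep = "")
  cat("provenance: ", x$provenance, "\n", sep = "")
  invisible(x)
}

#' Number of reports in a report set
#' @param rs A [report_set()].
#' @return Integer count of reports.
#' @export
n_reports <- function(rs) {
  stopifnot(inherits(rs, "report_set"))
  nrow(rs$demo)
}

# Convert reported age to years. Missing unit with a present value is read as
# years (FAERS practice when the unit code is absent) with a warning.
age_to_years <- function(value, unit) {
  value <- as.numeric(value)
  if (any(!is.na(value) & value < 0)) {
    stop("age_value must be non-negative", call. = FALSE)
  }
  unitless <- !is.na(value) & is.na(unit)
  if (any(unitless)) {
    warning(sum(unitless), " report(s) have an age value but no unit; ",
            "treating as years", call. = FALSE)
    unit[unitless] <- "years"
  }
  out <- rep(NA_real_, length(value))
  out[!is.na(unit) & unit == "years"] <- value[!is.na(unit) & unit == "years"]
  mo <- !is.na(unit) & unit == "months"
  out[mo] <- value[mo] / 12
  dy <- !is.na(unit) & unit == "days"
  out[dy] <- value[dy] / 365.25
  out
}

check_columns <- function(df, required, table_name) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop(sprintf("%s table is missing required column(s): %s",
                 table_name, paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

#' Keep one report per case
#'
#' FAERS cases are submitted repeatedly as versioned follow-up reports;
#' disproportionality counts are per case, so only the latest version of each
#' case is retained: the record with the highest `version`, ties broken by
#' the lexicographically greatest `report_id`.
#'
#' @param rs A [report_set()].
#' @return A `report_set` with exactly one record per `case_id`. Idempotent.
#' @export
deduplicate <- function(rs) {
  stopifnot(inherits(rs, "report_set"))
  keep <- rs$demo |>
    dplyr::arrange(.data$case_id, dplyr::desc(.data$version),
                   dplyr::desc(.data$report_id)) |>
    dplyr::distinct(.data$case_id, .keep_all = TRUE)
  ids <- keep$report_id
  report_set(
    demo = keep[setdiff(names(keep), "age_years")],
    drugs = rs$drugs[rs$drugs$report_id %in% ids, ],
    reactions = rs$reactions[rs$reactions$report_id %in% ids, ],
    provenance = rs$provenance
  )
}
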