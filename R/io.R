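#' Read a spontaneous-report database from its three-table layout
#'
#' The on-disk representation mirrors the structure of spontaneous-report
#' databases: a demographics table (one row per report), a drug table (one
#' row per verbatim drug mention) and a reaction table (one row per reported
#' Preferred Term). Files are delimited text with a header row, UTF-8.
#'
#' @param demo_path Path to the demographics table with columns
#'   `report_id, case_id, version, sex, age_value, age_unit, country`.
#' @param drug_path Path to the drug table with columns
#'   `report_id, drug_name`.
#' @param reac_path Path to the reaction table with columns `report_id, pt`.
#' @param delimiter Field delimiter, `","` (default) or `"\t"`.
#' @param provenance Label stored on the returned set; defaults to the
#'   demo file path.
#'
#' @return A validated [report_set()]. Rows in the drug or reaction table
#'   that reference an unknown `report_id`, reports with no drug mention,
#'   and missing required columns are all errors.
#' @export
read_report_tables <- function(demo_path, drug_path, reac_path,
                               delimiter = ",",
                               provenance = demo_path) {
  for (p in c(demo_path, drug_path, reac_path)) {
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  }
  # validate headers before the typed parse so a missing column yields a
  # format error naming it rather than a parser warning
  header_of <- function(p) names(readr::read_delim(
    p, delim = delimiter, n_max = 0,
    col_types = readr::cols(.default = readr::col_character()),
    show_col_types = FALSE))
  hdr <- header_of(demo_path)
  missing <- setdiff(c("report_id", "case_id", "version", "sex",
                       "age_value", "age_unit", "country"), hdr)
  if (length(missing) > 0) {
    stop("demo table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  demo <- readr::read_delim(
    demo_path, delim = delimiter, col_types = readr::cols(
      report_id = readr::col_character(), case_id = readr::col_character(),
      version = readr::col_integer(), sex = readr::col_character(),
      age_value = readr::col_double(), age_unit = readr::col_character(),
      country = readr::col_character(), .default = readr::col_character()
    ), na = c("", "NA"), progress = FALSE, show_col_types = FALSE
  )
  drugs <- readr::read_delim(
    drug_path, delim = delimiter,
    col_types = readr::cols(.default = readr::col_character()),
    na = character(), progress = FALSE, show_col_types = FALSE
  )
  reactions <- readr::read_delim(
    reac_path, delim = delimiter,
    col_types = readr::cols(.default = readr::col_character()),
    na = character(), progress = FALSE, show_col_types = FALSE
  )
  check_columns(demo, c("report_id", "case_id", "version", "sex",
                        "age_value", "age_unit", "country"), "demo")
  check_columns(drugs, c("report_id", "drug_name"), "drug")
  check_columns(reactions, c("report_id", "pt"), "reac")
  report_set(demo, drugs, reactions, provenance = provenance)
}

#' Write a report set back to the three-table layout
#'
#' Inverse of [read_report_tables()]: writes `demo.csv`, `drug.csv` and
#' `reac.csv` into `dir`. A read of the written files round-trips the set
#' (up to the derived `age_years` column, which is recomputed on read).
#'
#' @param rs A [report_set()].
#' @param dir Output directory, created if needed.
#' @param delimiter Field delimiter, `","` (default) or `"\t"`.
#' @return Invisibly, the three file paths.
#' @export
write_report_tables <- function(rs, dir, delimiter = ",") {
  stopifnot(inherits(rs, "report_set"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("demo.csv", "drug.csv", "reac.csv"))
  readr::write_delim(rs$demo[c("report_id", "case_id", "version", "sex",
                               "age_value", "age_unit", "country")],
                     paths[1], delim = delimiter, na = "")
  readr::write_delim(rs$drugs, paths[2], delim = delimiter, na = "")
  readr::write_delim(rs$reactions, paths[3], delim = delimiter, na = "")
  invisible(paths)
}

#' Round half away from zero
#'
#' Commercial rounding at `digits` decimals (0.5 always rounds up), as used
#' for the printed percentages and statistics of signal tables. Base
#' `round()` rounds half to even, which disagrees on exact halves.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  # nudge guards values like 5.445 that sit a hair below the exact half in
  # binary floating point
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

fmt2 <- function(x) {
  ifelse(is.na(x), "",
         ifelse(is.infinite(x), "Inf",
                sprintf("%.2f", round_half_up(x, 2))))
}

#' Write a signal table to a delimited file
#'
#' Serializes screening results in the layout of published signal tables:
#' one row per (drug, event) with the case count, PRR, chi-squared and the
#' positive/negative classification. PRR and chi-squared are printed to two
#' decimals, rounding half up.
#'
#' @param results Tibble of signal results with columns `drug_class`,
#'   `drug`, `event`, `n_cases`, `prr`, `chi2`, `positive` (as produced by
#'   [run_screen()] / [group_by_class()]). May be empty.
#' @param out_path Output file path.
#' @param delimiter Field delimiter, `","` (default) or `"\t"`.
#' @return Invisibly, `out_path`.
#' @export
write_signal_table <- function(results, out_path, delimiter = ",") {
  results <- tibble::as_tibble(results)
  if (nrow(results) == 0) {
    out <- tibble::tibble(
      drug_class = character(), drug_name = character(), event = character(),
      N = integer(), PRR = character(), chi2 = character(),
      signal = character()
    )
    readr::write_delim(out, out_path, delim = delimiter, na = "")
    return(invisible(out_path))
  }
  out <- tibble::tibble(
    drug_class = as.character(results$drug_class),
    drug_name = as.character(results$drug),
    event = as.character(results$event),
    N = as.integer(results$n_cases),
    PRR = fmt2(results$prr),
    chi2 = fmt2(results$chi2),
    signal = ifelse(results$positive, "positive", "negative")
  )
  readr::write_delim(out, out_path, delim = delimiter, na = "")
  invisible(out_path)
}
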