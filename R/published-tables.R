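#' Paths to packaged example and reference data
#'
#' @param file File name under the package's `extdata/` directory; with no
#'   argument, lists the available files.
#' @return A file path (or a character vector of file names).
#' @export
prrscreen_example <- function(file = NULL) {
  base <- system.file("extdata", package = "prrscreen", mustWork = TRUE)
  if (is.null(file)) {
    return(list.files(base, recursive = TRUE))
  }
  path <- file.path(base, file)
  if (!file.exists(path)) stop("no packaged file: ", file, call. = FALSE)
  path
}

published_event_labels <- c("hyperuricaemia", "gout", "gouty arthritis",
                            "gouty tophus", "urate nephropathy")

#' Transcribed signal tables from a published FAERS screen
#'
#' The packaged reference tables transcribe the per-event signal tables of
#' a published FAERS disproportionality analysis of antihypertensive drugs
#' and urate-related adverse events: one row per positive (drug, event)
#' signal with the reported case count N, PRR and chi-squared. They serve
#' as regression fixtures for the classification, counting and overlap
#' machinery — the underlying 2x2 tables would require the full FAERS
#' extract and are not reproducible from the printed values.
#'
#' @return Named list (event label -> tibble with columns `drug_class`,
#'   `drug_name`, `N`, `PRR`, `chi2`) for the five urate-related events.
#' @export
published_signal_tables <- function() {
  files <- paste0("published_tables/signals_",
                  gsub(" ", "_", published_event_labels), ".csv")
  tabs <- lapply(files, function(f) {
    readr::read_csv(prrscreen_example(f),
                    col_types = readr::cols(
                      drug_class = readr::col_character(),
                      drug_name = readr::col_character(),
                      N = readr::col_integer(),
                      PRR = readr::col_double(),
                      chi2 = readr::col_double()
                    ), progress = FALSE)
  })
  stats::setNames(tabs, published_event_labels)
}

#' Transcribed report-overview counts from a published FAERS screen
#'
#' Per-event report counts broken down by sex, age bin and reporter
#' country, as published, together with the printed percentages. Used to
#' regression-test the percentage arithmetic.
#'
#' @return Tibble with columns `event`, `breakdown`, `stratum`, `count`,
#'   `published_pct` (the `total` rows carry the event's report total).
#' @export
published_overview_counts <- function() {
  readr::read_csv(prrscreen_example("published_tables/report_overview.csv"),
                  col_types = readr::cols(
                    event = readr::col_character(),
                    breakdown = readr::col_character(),
                    stratum = readr::col_character(),
                    count = readr::col_integer(),
                    published_pct = readr::col_double()
                  ), progress = FALSE)
}
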