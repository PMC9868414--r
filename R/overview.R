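#' Format a count as a percentage string
#'
#' `"NN.NN%"` with two decimals, rounding half up — the convention of
#' published report-overview tables (960 of 1727 prints as `"55.59%"`).
#'
#' @param count Integer, `0 <= count <= total`.
#' @param total Positive integer.
#' @return Character vector like `"55.59%"`.
#' @export
format_percentage <- function(count, total) {
  if (any(total <= 0)) stop("total must be positive", call. = FALSE)
  if (any(count < 0 | count > total)) {
    stop("count must be between 0 and total", call. = FALSE)
  }
  sprintf("%.2f%%", round_half_up(100 * count / total, 2))
}

age_bin_labels <- c("0-17 years", "18-40 years", "41-65 years",
                    ">65 years", "unknown")

# integer-year bins behind the published "0-17 / 18-40 / 41-65 / >65"
# labels: [0,18), [18,41), [41,66), [66,Inf) on age in years
age_bin <- function(age_years) {
  out <- rep("unknown", length(age_years))
  ok <- !is.na(age_years)
  out[ok & age_years < 18] <- "0-17 years"
  out[ok & age_years >= 18 & age_years < 41] <- "18-40 years"
  out[ok & age_years >= 41 & age_years < 66] <- "41-65 years"
  out[ok & age_years >= 66] <- ">65 years"
  out
}

country_group <- function(country) {
  out <- rep("Unknown", length(country))
  ok <- !is.na(country) & nzchar(trimws(country))
  us <- ok & normalize_name(country) %in% c("united states", "us", "usa")
  out[us] <- "United States"
  out[ok & !us] <- "Other countries"
  out
}

#' Per-event report overview: sex, age and reporter country
#'
#' Selects the reports carrying the event and tabulates them by sex
#' (male / female / unknown), age bin (0-17, 18-40, 41-65, >65 years,
#' unknown — integer-year boundaries, so a 65-year-old is in 41-65) and
#' reporter country (United States / other countries / unknown). Counts in
#' each breakdown sum to the event's report total; percentages are of that
#' total, rounded half up to two decimals.
#'
#' @param rs A deduplicated [report_set()].
#' @param event An [event_definition()].
#' @return An object of class `overview_table`: a tibble with columns
#'   `event, breakdown, stratum, count, pct, pct_label` plus an attribute
#'   `total_reports`.
#' @export
summarize_event <- function(rs, event) {
  stopifnot(inherits(rs, "report_set"), inherits(event, "event_definition"))
  sel <- reports_with_event(rs, event)
  demo <- rs$demo[sel, ]
  total <- nrow(demo)

  strata <- list(
    sex = list(values = ifelse(is.na(demo$sex), "unknown", demo$sex),
               levels = c("male", "female", "unknown")),
    age = list(values = age_bin(demo$age_years),
               levels = age_bin_labels),
    country = list(values = country_group(demo$country),
                   levels = c("United States", "Other countries", "Unknown"))
  )
  rows <- lapply(names(strata), function(bk) {
    s <- strata[[bk]]
    counts <- vapply(s$levels, function(lv) sum(s$values == lv), 0L)
    tibble::tibble(
      event = event$label,
      breakdown = bk,
      stratum = s$levels,
      count = as.integer(counts),
      pct = if (total > 0) round_half_up(100 * counts / total, 2) else
        NA_real_,
      pct_label = if (total > 0) format_percentage(counts, total) else
        NA_character_
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "total_reports") <- total
  class(out) <- c("overview_table", class(out))
  out
}

#' Write per-event overview tables
#'
#' One row per (event, breakdown, stratum), mirroring the published
#' overview layout.
#'
#' @param overviews List of [summarize_event()] results (or a single one).
#' @param out_path Output file path.
#' @param delimiter Field delimiter (default `","`).
#' @return Invisibly, `out_path`.
#' @export
write_overview_table <- function(overviews, out_path, delimiter = ",") {
  if (inherits(overviews, "overview_table")) overviews <- list(overviews)
  rows <- lapply(overviews, function(ov) {
    tot <- attr(ov, "total_reports")
    df <- tibble::as_tibble(ov)
    df$total_reports <- tot
    df
  })
  out <- dplyr::bind_rows(rows)
  out <- out[c("event", "total_reports", "breakdown", "stratum",
               "count", "pct_label")]
  readr::write_delim(out, out_path, delim = delimiter, na = "")
  invisible(out_path)
}
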