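#' Screen every (drug, event) pair for disproportionality signals
#'
#' Batch-runs the contingency / PRR / chi-squared / Evans-classification
#' chain over the full cross of the vocabulary's canonical drugs and the
#' supplied event definitions. Pairs whose statistics are undefined (a zero
#' marginal: the drug is never reported, the event never occurs, or every
#' report carries the event) are kept in the output as negative with a
#' reason code — never dropped silently.
#'
#' @param rs A deduplicated [report_set()].
#' @param vocab A [load_vocabulary()] result.
#' @param events List of [event_definition()] objects (e.g. from
#'   [load_event_definitions()]).
#' @param yates Continuity-correct the chi-squared statistic (default
#'   `TRUE`; see [compute_chi2()]).
#' @param continuity Constant passed to [compute_prr()] (default 0).
#' @return An object of class `screen_result`: a list with
#'   `per_event` (named list of tibbles, one row per drug with columns
#'   `drug_class, drug, event, a, b, c, d, n_cases, prr, chi2, positive,
#'   reason`) and `overlap` (named list: canonical drugname -> character
#'   vector of event labels with a positive signal).
#' @export
run_screen <- function(rs, vocab, events, yates = TRUE, continuity = 0) {
  stopifnot(inherits(rs, "report_set"), inherits(vocab, "drug_vocabulary"))
  if (n_reports(rs) == 0) {
    stop("empty report set: background population undefined", call. = FALSE)
  }
  if (length(events) == 0) stop("no events to screen", call. = FALSE)
  events <- stats::setNames(events, vapply(events, `[[`, "", "label"))

  n <- n_reports(rs)
  drug_hit <- vapply(vocab$entries$canonical,
                     function(dr) reports_with_drug(rs, vocab, dr),
                     logical(n))
  event_hit <- vapply(events, function(ev) reports_with_event(rs, ev),
                      logical(n))
  # columns of the vapply results are per-drug / per-event membership masks
  if (n == 1) {
    drug_hit <- matrix(drug_hit, nrow = 1,
                       dimnames = list(NULL, vocab$entries$canonical))
    event_hit <- matrix(event_hit, nrow = 1,
                        dimnames = list(NULL, names(events)))
  }

  per_event <- lapply(names(events), function(lab) {
    e <- event_hit[, lab]
    rows <- lapply(seq_len(nrow(vocab$entries)), function(i) {
      d <- drug_hit[, i]
      a <- sum(d & e); b <- sum(d & !e); c <- sum(!d & e); d4 <- sum(!d & !e)
      prr <- NA_real_; chi2 <- NA_real_; reason <- "ok"
      if (a + b == 0) {
        reason <- "drug not reported"
      } else if (c + d4 == 0) {
        reason <- "no background"
      } else if (a + c == 0) {
        reason <- "no cases"
        prr <- 0
      } else if (b + d4 == 0) {
        reason <- "event in every report"
        prr <- compute_prr(contingency_table(a, b, c, d4), continuity)
      } else {
        tab <- contingency_table(a, b, c, d4)
        prr <- compute_prr(tab, continuity)
        chi2 <- compute_chi2(tab, yates = yates)
      }
      tibble::tibble(
        drug_class = vocab$entries$drug_class[i],
        drug = vocab$entries$canonical[i],
        event = lab,
        a = a, b = b, c = c, d = d4,
        n_cases = a, prr = prr, chi2 = chi2,
        positive = classify_signal(a, prr, chi2),
        reason = reason
      )
    })
    dplyr::bind_rows(rows)
  })
  names(per_event) <- names(events)
  new_screen_result(per_event)
}

new_screen_result <- function(per_event) {
  pos <- dplyr::bind_rows(per_event) |> dplyr::filter(.data$positive)
  overlap <- split(pos$event, pos$drug)
  structure(list(per_event = per_event, overlap = overlap),
            class = "screen_result")
}

#' Assemble a screen result from published-style signal tables
#'
#' Signal tables as printed in the pharmacovigilance literature carry only
#' (drug class, drug name, N, PRR, chi-squared) per row. This constructor
#' re-applies the Evans classification to such rows, so the counting and
#' overlap machinery ([count_positive()], [overlap_histogram()]) can be run
#' on transcribed published tables as well as on fresh screens.
#'
#' @param tables Named list (event label -> tibble with columns
#'   `drug_class`, `drug_name` (or `drug`), `N`, `PRR`, `chi2`).
#' @return A `screen_result`; the 2x2 cells, unavailable in printed tables,
#'   are `NA`.
#' @export
screen_result_from_tables <- function(tables) {
  if (is.null(names(tables)) || any(!nzchar(names(tables)))) {
    stop("tables must be a named list (event label -> table)", call. = FALSE)
  }
  per_event <- lapply(names(tables), function(lab) {
    df <- tibble::as_tibble(tables[[lab]])
    if (!"drug" %in% names(df) && "drug_name" %in% names(df)) {
      df$drug <- df$drug_name
    }
    check_columns(df, c("drug_class", "drug", "N", "PRR", "chi2"), lab)
    tibble::tibble(
      drug_class = as.character(df$drug_class),
      drug = as.character(df$drug),
      event = lab,
      a = NA_real_, b = NA_real_, c = NA_real_, d = NA_real_,
      n_cases = as.numeric(df$N),
      prr = as.numeric(df$PRR),
      chi2 = as.numeric(df$chi2),
      positive = classify_signal(as.numeric(df$N), as.numeric(df$PRR),
                                 as.numeric(df$chi2)),
      reason = "ok"
    )
  })
  names(per_event) <- names(tables)
  new_screen_result(per_event)
}

#' @export
print.screen_result <- function(x, ...) {
  np <- vapply(x$per_event, function(df) sum(df$positive), 0L)
  cat("<screen_result> ", length(x$per_event), " event(s), ",
      nrow(x$per_event[[1]]), " drug(s)\n", sep = "")
  for (lab in names(np)) {
    cat("  ", lab, ": ", np[[lab]], " positive signal(s)\n", sep = "")
  }
  invisible(x)
}

#' Number of drugs with a positive signal for an event
#'
#' @param result A `screen_result`.
#' @param event_label Label of a screened event.
#' @return Integer count of drugs classified positive.
#' @export
count_positive <- function(result, event_label) {
  stopifnot(inherits(result, "screen_result"))
  if (!event_label %in% names(result$per_event)) {
    stop("event not screened: ", event_label, call. = FALSE)
  }
  sum(result$per_event[[event_label]]$positive)
}

#' Cross-event overlap histogram
#'
#' How many drugs have a positive signal for exactly k of the screened
#' events — the "drugs with positive signal for more than one AE" summary.
#'
#' @param result A `screen_result`.
#' @return An object of class `overlap_histogram`: a list with
#'   `histogram` (tibble `n_events`, `n_drugs`, `drugs` — a list-column of
#'   sorted drug names — for every k from 1 to the number of screened
#'   events), `n_ge1` (drugs with at least one positive signal) and `n_ge2`
#'   (drugs positive for more than one event).
#' @export
overlap_histogram <- function(result) {
  stopifnot(inherits(result, "screen_result"))
  k_max <- length(result$per_event)
  counts <- vapply(result$overlap, length, 0L)
  hist <- tibble::tibble(
    n_events = seq_len(k_max),
    n_drugs = vapply(seq_len(k_max),
                     function(k) sum(counts == k), 0L),
    drugs = lapply(seq_len(k_max),
                   function(k) sort(names(counts)[counts == k]))
  )
  structure(list(histogram = hist,
                 n_ge1 = sum(counts >= 1),
                 n_ge2 = sum(counts >= 2)),
            class = "overlap_histogram")
}

#' @export
print.overlap_histogram <- function(x, ...) {
  cat("<overlap_histogram> ", x$n_ge1, " drug(s) with >=1 positive signal, ",
      x$n_ge2, " with >=2\n", sep = "")
  for (i in seq_len(nrow(x$histogram))) {
    cat("  exactly ", x$histogram$n_events[i], " event(s): ",
        x$histogram$n_drugs[i], " drug(s)\n", sep = "")
  }
  invisible(x)
}

#' Signal-table rows grouped and ordered by drug class
#'
#' Reproduces the published table layout: rows (drug class, drug, N, PRR,
#' chi-squared) ordered by the vocabulary's fixed class display order
#' (diuretics first, compound preparations last) and, within a class, by
#' vocabulary entry order.
#'
#' @param result A `screen_result`.
#' @param vocab The [load_vocabulary()] result used for the screen; its
#'   `class_order` defines the class ordering.
#' @param event_label Label of a screened event.
#' @param positives_only Keep only positive signals (default `TRUE`,
#'   the published-table view).
#' @return Tibble with columns `drug_class, drug, event, n_cases, prr,
#'   chi2, positive, reason`.
#' @export
group_by_class <- function(result, vocab, event_label,
                           positives_only = TRUE) {
  stopifnot(inherits(result, "screen_result"),
            inherits(vocab, "drug_vocabulary"))
  if (!event_label %in% names(result$per_event)) {
    stop("event not screened: ", event_label, call. = FALSE)
  }
  df <- result$per_event[[event_label]]
  if (positives_only) df <- df[df$positive, ]
  class_rank <- match(df$drug_class, vocab$class_order)
  vocab_rank <- match(df$drug, vocab$entries$canonical)
  df <- df[order(class_rank, vocab_rank), ]
  df[c("drug_class", "drug", "event", "n_cases", "prr", "chi2",
       "positive", "reason")]
}

#' Write the cross-event overlap table
#'
#' One row per drug with at least one positive signal: the number of events
#' with a positive signal and their labels.
#'
#' @param result A `screen_result`.
#' @param out_path Output file path.
#' @param delimiter Field delimiter (default `","`).
#' @return Invisibly, `out_path`.
#' @export
write_overlap_table <- function(result, out_path, delimiter = ",") {
  stopifnot(inherits(result, "screen_result"))
  drugs <- sort(names(result$overlap))
  out <- tibble::tibble(
    drug = drugs,
    n_positive_events = vapply(result$overlap[drugs], length, 0L),
    events = vapply(result$overlap[drugs],
                    function(e) paste(sort(e), collapse = "; "), "")
  )
  out <- out[order(-out$n_positive_events, out$drug), ]
  readr::write_delim(out, out_path, delim = delimiter, na = "")
  invisible(out_path)
}
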