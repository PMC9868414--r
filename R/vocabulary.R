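#' Drug vocabulary: verbatim names to canonical drugnames
#'
#' Spontaneous reports carry free-text drug names — brand names, generic
#' names, abbreviations, dose-qualified strings. A `drug_vocabulary` maps
#' each known verbatim form to one canonical drugname carrying a drug class,
#' the role the Drugs@FDA / DrugBank dictionaries play in FAERS front-ends.
#' Matching is exact after case-folding and whitespace normalization; there
#' is deliberately no fuzzy or substring matching, which would inflate
#' signal counts unpredictably.
#'
#' @param path Path to a YAML vocabulary file with top-level keys
#'   `class_order` (display order of drug classes) and `drugs`, a list of
#'   entries with fields `canonical`, `class` and optional `synonyms`.
#'
#' @return An object of class `drug_vocabulary`: a list with
#'   `entries` (tibble `canonical`, `drug_class`, in file order),
#'   `lookup` (named character vector, normalized synonym -> canonical) and
#'   `class_order` (character vector).
#' @export
load_vocabulary <- function(path) {
  if (!file.exists(path)) stop("vocabulary file not found: ", path,
                               call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw$drugs) || length(raw$drugs) == 0) {
    stop("vocabulary file has no drug entries: ", path, call. = FALSE)
  }
  entries <- lapply(raw$drugs, function(e) {
    if (is.null(e$canonical) || !nzchar(trimws(e$canonical))) {
      stop("vocabulary entry without a canonical name", call. = FALSE)
    }
    if (is.null(e$class) || !nzchar(trimws(e$class))) {
      stop("vocabulary entry '", e$canonical, "' has no drug class",
           call. = FALSE)
    }
    list(canonical = as.character(e$canonical),
         drug_class = as.character(e$class),
         synonyms = as.character(e$synonyms %||% character()))
  })
  canonical <- vapply(entries, `[[`, "", "canonical")
  drug_class <- vapply(entries, `[[`, "", "drug_class")
  if (anyDuplicated(normalize_name(canonical))) {
    dup <- canonical[duplicated(normalize_name(canonical))]
    stop("duplicate canonical name(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  class_order <- as.character(raw$class_order %||% unique(drug_class))

  syn <- unlist(lapply(entries, function(e) {
    s <- unique(c(e$canonical, e$synonyms))
    stats::setNames(rep(e$canonical, length(s)), normalize_name(s))
  }))
  keys <- names(syn)
  if (anyDuplicated(keys)) {
    dup_keys <- unique(keys[duplicated(keys)])
    claims <- vapply(dup_keys, function(k) {
      paste0("'", k, "' -> {", paste(unique(syn[keys == k]), collapse = ", "),
             "}")
    }, "")
    stop("synonym(s) map to more than one canonical name: ",
         paste(claims, collapse = "; "), call. = FALSE)
  }

  structure(
    list(entries = tibble::tibble(canonical = canonical,
                                  drug_class = drug_class,
                                  synonyms = lapply(entries, `[[`,
                                                    "synonyms")),
         lookup = syn,
         class_order = class_order),
    class = "drug_vocabulary"
  )
}

#' @export
print.drug_vocabulary <- function(x, ...) {
  cat("<drug_vocabulary> ", nrow(x$entries), " drugs in ",
      length(unique(x$entries$drug_class)), " classes, ",
      length(x$lookup), " resolvable names\n", sep = "")
  invisible(x)
}

# case-fold and collapse runs of whitespace; the normal form used for every
# drug-name and PT comparison in the package
normalize_name <- function(x) {
  tolower(gsub("[[:space:]]+", " ", trimws(x)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Map verbatim drug names to canonical drugnames
#'
#' Exact lookup after normalization (case-insensitive, whitespace
#' collapsed). Unrecognized names map to `NA` — an explicit "unmapped"
#' value, never a guess.
#'
#' @param vocab A [load_vocabulary()] result.
#' @param verbatim Character vector of verbatim drug-name strings.
#' @return Character vector of canonical names, `NA` where unmapped.
#' @export
map_drug_name <- function(vocab, verbatim) {
  stopifnot(inherits(vocab, "drug_vocabulary"))
  unname(vocab$lookup[normalize_name(verbatim)])
}

#' Which reports mention a drug
#'
#' A report mentions the drug if any of its verbatim drug strings maps to
#' the canonical name; multiple mentions of the same drug in one report
#' count once (report-level counting).
#'
#' @param rs A [report_set()].
#' @param vocab A [load_vocabulary()] result.
#' @param canonical_name A canonical name present in `vocab`.
#' @return Logical vector aligned with the rows of `rs$demo`.
#' @export
reports_with_drug <- function(rs, vocab, canonical_name) {
  stopifnot(inherits(rs, "report_set"))
  if (!canonical_name %in% vocab$entries$canonical) {
    stop("unknown canonical name: ", canonical_name, call. = FALSE)
  }
  mapped <- map_drug_name(vocab, rs$drugs$drug_name)
  ids <- unique(rs$drugs$report_id[!is.na(mapped) & mapped == canonical_name])
  rs$demo$report_id %in% ids
}

#' Does a single report mention a drug
#'
#' @inheritParams reports_with_drug
#' @param report_id The report to test.
#' @return `TRUE` iff any drug mention of that report maps to
#'   `canonical_name`.
#' @export
report_has_drug <- function(rs, vocab, report_id, canonical_name) {
  hit <- reports_with_drug(rs, vocab, canonical_name)
  idx <- match(report_id, rs$demo$report_id)
  if (is.na(idx)) stop("unknown report_id: ", report_id, call. = FALSE)
  hit[idx]
}

#' Adverse-event definition as a Preferred Term set
#'
#' An adverse event of interest is defined by one or more MedDRA Preferred
#' Terms; a report carries the event if any of its reaction PTs is in the
#' set (case-insensitive, whitespace-normalized).
#'
#' @param label Event label, e.g. `"hyperuricaemia"`.
#' @param pts Non-empty character vector of Preferred Terms.
#' @return An object of class `event_definition`.
#' @export
event_definition <- function(label, pts) {
  pts <- as.character(pts)
  if (length(pts) == 0 || any(!nzchar(trimws(pts)))) {
    stop("event '", label, "' needs a non-empty set of Preferred Terms",
         call. = FALSE)
  }
  structure(list(label = as.character(label),
                 pts = unique(pts),
                 pts_norm = unique(normalize_name(pts))),
            class = "event_definition")
}

#' Load event definitions from a YAML file
#'
#' @param path YAML file with a top-level `events` list of
#'   `{label, pts: [...]}` entries.
#' @return Named list of [event_definition()] objects (names = labels).
#' @export
load_event_definitions <- function(path) {
  if (!file.exists(path)) stop("event file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw$events) || length(raw$events) == 0) {
    stop("event file has no event entries: ", path, call. = FALSE)
  }
  evs <- lapply(raw$events, function(e) event_definition(e$label, e$pts))
  labels <- vapply(evs, `[[`, "", "label")
  if (anyDuplicated(labels)) {
    stop("duplicate event label(s): ",
         paste(labels[duplicated(labels)], collapse = ", "), call. = FALSE)
  }
  stats::setNames(evs, labels)
}

#' Which reports carry an event
#'
#' @param rs A [report_set()].
#' @param event An [event_definition()].
#' @return Logical vector aligned with the rows of `rs$demo`; `FALSE` for
#'   reports with no reaction PTs.
#' @export
reports_with_event <- function(rs, event) {
  stopifnot(inherits(rs, "report_set"), inherits(event, "event_definition"))
  hit <- normalize_name(rs$reactions$pt) %in% event$pts_norm
  ids <- unique(rs$reactions$report_id[hit])
  rs$demo$report_id %in% ids
}

#' Does a single report carry an event
#'
#' @inheritParams reports_with_event
#' @param report_id The report to test.
#' @return `TRUE` iff any reaction PT of the report is in the event's set.
#' @export
report_has_event <- function(rs, event, report_id) {
  hit <- reports_with_event(rs, event)
  idx <- match(report_id, rs$demo$report_id)
  if (is.na(idx)) stop("unknown report_id: ", report_id, call. = FALSE)
  hit[idx]
}
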