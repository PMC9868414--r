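#' 2x2 contingency table for a (drug, event) pair
#'
#' Disproportionality analysis reduces each (drug, event) query to a 2x2
#' table over the deduplicated report set:
#'
#' |            | event | no event |
#' |------------|-------|----------|
#' | drug       |  a    |   b      |
#' | background |  c    |   d      |
#'
#' where the background is every report that does not mention the target
#' drug. Each report falls in exactly one cell, so `a + b + c + d` equals
#' the number of reports.
#'
#' @param a,b,c,d Non-negative integer cell counts.
#' @return An object of class `contingency_table`.
#' @export
contingency_table <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != round(cells))) {
    stop("cell counts must be non-negative integers", call. = FALSE)
  }
  structure(list(a = as.numeric(a), b = as.numeric(b),
                 c = as.numeric(c), d = as.numeric(d)),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  m <- matrix(c(x$a, x$b, x$c, x$d), 2, 2, byrow = TRUE,
              dimnames = list(c("drug", "background"),
                              c("event", "no event")))
  print(m)
  invisible(x)
}

#' Build the contingency table for a (drug, event) pair
#'
#' Classifies every report of a deduplicated set by
#' [reports_with_drug()] x [reports_with_event()].
#'
#' @param rs A deduplicated [report_set()].
#' @param vocab A [load_vocabulary()] result.
#' @param drug Canonical drugname present in `vocab`.
#' @param event An [event_definition()].
#' @return A [contingency_table()] with `a + b + c + d == n_reports(rs)`.
#' @export
build_contingency <- function(rs, vocab, drug, event) {
  stopifnot(inherits(rs, "report_set"))
  if (n_reports(rs) == 0) {
    stop("empty report set: background population undefined", call. = FALSE)
  }
  has_d <- reports_with_drug(rs, vocab, drug)
  has_e <- reports_with_event(rs, event)
  contingency_table(
    a = sum(has_d & has_e),
    b = sum(has_d & !has_e),
    c = sum(!has_d & has_e),
    d = sum(!has_d & !has_e)
  )
}

#' Proportional reporting ratio
#'
#' `PRR = [a / (a + b)] / [c / (c + d)]`: the event's reporting frequency
#' among reports of the target drug divided by its frequency in the
#' background. `PRR = 2` means the event is reported twice as frequently
#' with the drug as in the background population.
#'
#' @param t A [contingency_table()].
#' @param continuity Haldane-style constant added to every cell before the
#'   ratio; default `0` (no correction, so `PRR = Inf` when the event never
#'   occurs in the background). `0.5` gives finite values for zero cells.
#' @return Non-negative real; with `continuity = 0`, `0` when `a = 0` and
#'   `Inf` when `c = 0` and `a > 0`. Errors when a row margin is empty
#'   (`a + b = 0` or `c + d = 0`), where the ratio is undefined.
#' @export
compute_prr <- function(t, continuity = 0) {
  stopifnot(inherits(t, "contingency_table"), continuity >= 0)
  if (t$a + t$b == 0) stop("no reports mention the drug: PRR undefined",
                           call. = FALSE)
  if (t$c + t$d == 0) stop("empty background: PRR undefined", call. = FALSE)
  a <- t$a + continuity; b <- t$b + continuity
  c <- t$c + continuity; d <- t$d + continuity
  if (a == 0) return(0)
  if (c == 0) return(Inf)
  (a / (a + b)) / (c / (c + d))
}

#' Chi-squared statistic of a 2x2 table
#'
#' Pearson statistic `n (ad - bc)^2 / [(a+b)(c+d)(a+c)(b+d)]`; with
#' `yates = TRUE` the Yates continuity correction
#' `n (|ad - bc| - n/2)^2 / [same denominator]`, floored at 0 when
#' `|ad - bc| <= n/2`. The corrected form is the convention of the Evans
#' signal criterion and of OpenVigil-style FAERS front-ends; the published
#' threshold (chi-squared >= 4) is applied to whichever variant is chosen.
#'
#' @param t A [contingency_table()].
#' @param yates Apply the continuity correction (default `TRUE`).
#' @return Non-negative real. Errors when any marginal total is zero.
#' @export
compute_chi2 <- function(t, yates = TRUE) {
  stopifnot(inherits(t, "contingency_table"))
  a <- t$a; b <- t$b; c <- t$c; d <- t$d
  n <- a + b + c + d
  marg <- c(a + b, c + d, a + c, b + d)
  if (any(marg == 0)) {
    stop("zero marginal total: chi-squared undefined", call. = FALSE)
  }
  dev <- abs(a * d - b * c)
  if (yates) {
    dev <- max(dev - n / 2, 0)
  }
  n * dev^2 / prod(marg)
}

#' Evans positive-signal classification
#'
#' The signal-detection rule for spontaneous-report disproportionality:
#' a (drug, event) pair is a positive signal iff it has three or more
#' cases, PRR of two or greater, and chi-squared of at least four. All
#' three boundaries are inclusive. Vectorized.
#'
#' @param n_cases Case count (the `a` cell).
#' @param prr PRR value (may be `Inf`).
#' @param chi2 Chi-squared value.
#' @return Logical; `NA` inputs give `FALSE` (no evidence, no signal).
#' @export
classify_signal <- function(n_cases, prr, chi2) {
  out <- n_cases >= 3 & prr >= 2 & chi2 >= 4
  out[is.na(out)] <- FALSE
  out
}
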