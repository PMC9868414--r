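#' Configuration for the synthetic report-database generator
#'
#' Describes a FAERS-like spontaneous-report database with known ground
#' truth: per-drug reporting marginals, per-PT background reporting
#' probabilities, and planted (drug, PT) associations that multiply the
#' event's reporting probability by `lambda` whenever the drug is present.
#' With `lambda = 1` everywhere, drugs and events are independent and every
#' true PRR is 1; a planted `lambda > 1` is (for rare events and otherwise
#' independent drugs) the pair's true PRR, so pipeline estimates can be
#' checked against [expected_prr()].
#'
#' @param n_reports Number of reports to generate.
#' @param vocab A [load_vocabulary()] result; its canonical drugs form the
#'   drug catalog and its synonyms feed verbatim-name rendering.
#' @param pt_catalog Character vector of Preferred Terms reports can carry
#'   (the study PTs plus background noise PTs).
#' @param drug_marginals Probability a report mentions each drug: scalar or
#'   named vector over canonical names.
#' @param background_event_prob Per-PT reporting probability for reports
#'   carrying no planted drug: scalar or named vector over `pt_catalog`.
#' @param planted Data frame with columns `drug`, `pt`, `lambda`
#'   (multiplier >= 0) or `NULL` for none. `lambda * background_event_prob`
#'   must not exceed 1.
#' @param sex_probs Named probabilities over `c("male","female","unknown")`.
#' @param age_bin_probs Named probabilities over
#'   `c("0-17","18-40","41-65",">65","missing")`; ages are drawn uniformly
#'   within the chosen bin (66–95 for `>65`), so bin assignment is exact.
#' @param country_probs Named probabilities over
#'   `c("United States","other","missing")`; "other" draws one of a few
#'   non-US country codes.
#' @param synonym_noise Probability a drug mention is rendered as a
#'   non-canonical synonym or case variant instead of the canonical name.
#' @param duplicate_case_prob Probability a case is submitted twice (a
#'   version-1 duplicate alongside the retained version-2 record), for
#'   exercising deduplication. Default 0.
#' @param seed Integer seed; generation is fully deterministic given the
#'   config.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_reports,
                             vocab,
                             pt_catalog,
                             drug_marginals = 0.02,
                             background_event_prob = 0.002,
                             planted = NULL,
                             sex_probs = c(male = 0.55, female = 0.35,
                                           unknown = 0.10),
                             age_bin_probs = c("0-17" = 0.05,
                                               "18-40" = 0.20,
                                               "41-65" = 0.35,
                                               ">65" = 0.15,
                                               "missing" = 0.25),
                             country_probs = c("United States" = 0.55,
                                               "other" = 0.40,
                                               "missing" = 0.05),
                             synonym_noise = 0.3,
                             duplicate_case_prob = 0,
                             seed = 1L) {
  stopifnot(inherits(vocab, "drug_vocabulary"),
            n_reports >= 0, length(pt_catalog) >= 1)
  drugs <- vocab$entries$canonical
  p_drug <- expand_named(drug_marginals, drugs, "drug_marginals")
  q_pt <- expand_named(background_event_prob, pt_catalog,
                       "background_event_prob")
  check_probs(p_drug, "drug_marginals")
  check_probs(q_pt, "background_event_prob")
  check_dist(sex_probs, c("male", "female", "unknown"), "sex_probs")
  check_dist(age_bin_probs, c("0-17", "18-40", "41-65", ">65", "missing"),
             "age_bin_probs")
  check_dist(country_probs, c("United States", "other", "missing"),
             "country_probs")
  if (synonym_noise < 0 || synonym_noise > 1) {
    stop("synonym_noise must be in [0, 1]", call. = FALSE)
  }
  if (duplicate_case_prob < 0 || duplicate_case_prob > 1) {
    stop("duplicate_case_prob must be in [0, 1]", call. = FALSE)
  }
  if (!is.null(planted)) {
    planted <- tibble::as_tibble(planted)
    check_columns(planted, c("drug", "pt", "lambda"), "planted")
    bad_drug <- setdiff(planted$drug, drugs)
    if (length(bad_drug) > 0) {
      stop("planted drug(s) not in vocabulary: ",
           paste(bad_drug, collapse = ", "), call. = FALSE)
    }
    bad_pt <- setdiff(planted$pt, pt_catalog)
    if (length(bad_pt) > 0) {
      stop("planted PT(s) not in pt_catalog: ",
           paste(bad_pt, collapse = ", "), call. = FALSE)
    }
    if (any(planted$lambda < 0)) {
      stop("planted lambda must be >= 0", call. = FALSE)
    }
    over <- planted$lambda * q_pt[planted$pt] > 1 + 1e-12
    if (any(over)) {
      stop("planted lambda x background_event_prob exceeds 1 for: ",
           paste(planted$drug[over], planted$pt[over], sep = "/",
                 collapse = ", "), call. = FALSE)
    }
  } else {
    planted <- tibble::tibble(drug = character(), pt = character(),
                              lambda = numeric())
  }
  structure(
    list(n_reports = as.integer(n_reports), vocab = vocab,
         pt_catalog = as.character(pt_catalog),
         drug_marginals = p_drug, background_event_prob = q_pt,
         planted = planted, sex_probs = sex_probs,
         age_bin_probs = age_bin_probs, country_probs = country_probs,
         synonym_noise = synonym_noise,
         duplicate_case_prob = duplicate_case_prob,
         seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

expand_named <- function(x, names_out, what) {
  if (length(x) == 1 && is.null(names(x))) {
    return(stats::setNames(rep(as.numeric(x), length(names_out)), names_out))
  }
  missing <- setdiff(names_out, names(x))
  if (length(missing) > 0) {
    stop(what, " missing entries for: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  stats::setNames(as.numeric(x[names_out]), names_out)
}

check_probs <- function(p, what) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop(what, " must be probabilities in [0, 1]", call. = FALSE)
  }
}

check_dist <- function(p, levels, what) {
  missing <- setdiff(levels, names(p))
  if (length(missing) > 0) {
    stop(what, " missing entries for: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  check_probs(p, what)
  if (abs(sum(p[levels]) - 1) > 1e-8) {
    stop(what, " must sum to 1", call. = FALSE)
  }
}

age_bin_ranges <- list("0-17" = c(0, 18), "18-40" = c(18, 41),
                       "41-65" = c(41, 66), ">65" = c(66, 95))
other_countries <- c("JP", "FR", "DE", "GB", "IT", "CN")

#' Generate a synthetic spontaneous-report database
#'
#' Samples a [report_set()] from a [synthetic_config()]: drug mentions are
#' independent Bernoulli draws per drug (reports with zero mentions are
#' resampled, so every report carries at least one drug); each PT is then
#' drawn with probability `background_event_prob * m`, where `m` is the
#' largest planted `lambda` among the report's drugs for that PT (1 if
#' none), capped at 1; demographics are drawn from the configured
#' distributions; each mention is rendered verbatim as the canonical name
#' or, with probability `synonym_noise`, as a random synonym or upper-case
#' variant. Deterministic given the config (including its seed).
#'
#' @param config A [synthetic_config()].
#' @return A [report_set()]; with `duplicate_case_prob > 0` some cases have
#'   two report versions and [deduplicate()] is needed before analysis.
#' @export
generate_reports <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_reports
  vocab <- config$vocab
  drugs <- vocab$entries$canonical
  m <- length(drugs)
  empty_rs <- function() report_set(
    demo = tibble::tibble(report_id = character(), case_id = character(),
                          version = integer(), sex = character(),
                          age_value = numeric(), age_unit = character(),
                          country = character()),
    drugs = tibble::tibble(report_id = character(), drug_name = character()),
    reactions = tibble::tibble(report_id = character(), pt = character()),
    provenance = "synthetic (empty)"
  )
  if (n == 0) return(empty_rs())

  withr::local_seed(config$seed)

  # drug presence: n x m Bernoulli matrix; resample all-zero rows so every
  # report mentions >= 1 drug without distorting which drugs fill the gap
  p <- config$drug_marginals
  present <- matrix(stats::runif(n * m) < rep(p, each = n), n, m)
  repeat {
    empty <- which(rowSums(present) == 0)
    if (length(empty) == 0) break
    present[empty, ] <- matrix(
      stats::runif(length(empty) * m) < rep(p, each = length(empty)),
      length(empty), m)
  }

  # per-report effective multiplier per PT: max planted lambda among the
  # report's drugs (1 if none)
  q <- config$background_event_prob
  pts <- config$pt_catalog
  reac_rows <- vector("list", length(pts))
  for (k in seq_along(pts)) {
    # multiplier = max lambda among the report's planted drugs for this PT,
    # or 1 when none is present (so lambda < 1 acts protectively)
    mult <- rep(1, n)
    pl <- config$planted[config$planted$pt == pts[k], ]
    if (nrow(pl) > 0) {
      maxlam <- rep(-Inf, n)
      any_pl <- rep(FALSE, n)
      for (j in seq_len(nrow(pl))) {
        di <- match(pl$drug[j], drugs)
        maxlam <- ifelse(present[, di], pmax(maxlam, pl$lambda[j]), maxlam)
        any_pl <- any_pl | present[, di]
      }
      mult <- ifelse(any_pl, maxlam, 1)
    }
    prob <- pmin(q[[k]] * mult, 1)
    hit <- stats::runif(n) < prob
    reac_rows[[k]] <- which(hit)
  }

  case_id <- sprintf("C%07d", seq_len(n))
  report_id <- paste0(case_id, "-2")

  sex <- sample(names(config$sex_probs), n, replace = TRUE,
                prob = config$sex_probs)
  bin <- sample(names(config$age_bin_probs), n, replace = TRUE,
                prob = config$age_bin_probs)
  age_value <- rep(NA_real_, n)
  for (b in names(age_bin_ranges)) {
    i <- bin == b
    r <- age_bin_ranges[[b]]
    age_value[i] <- floor(stats::runif(sum(i), r[1], r[2]))
  }
  age_unit <- ifelse(is.na(age_value), NA_character_, "years")
  cgrp <- sample(names(config$country_probs), n, replace = TRUE,
                 prob = config$country_probs)
  country <- rep(NA_character_, n)
  country[cgrp == "United States"] <- "United States"
  n_other <- sum(cgrp == "other")
  country[cgrp == "other"] <- sample(other_countries, n_other,
                                     replace = TRUE)

  # verbatim rendering of each mention
  mention <- which(present, arr.ind = TRUE)
  mention <- mention[order(mention[, 1], mention[, 2]), , drop = FALSE]
  verbatim <- drugs[mention[, 2]]
  use_var <- stats::runif(nrow(mention)) < config$synonym_noise
  if (any(use_var)) {
    variants <- lapply(seq_len(m), function(j) {
      unique(c(vocab$entries$synonyms[[j]], toupper(drugs[j])))
    })
    vi <- which(use_var)
    n_var <- vapply(variants[mention[vi, 2]], length, 0L)
    pick <- floor(stats::runif(length(vi)) * n_var) + 1
    verbatim[vi] <- mapply(function(v, k) v[k],
                           variants[mention[vi, 2]], pick)
  }

  demo <- tibble::tibble(
    report_id = report_id, case_id = case_id, version = 2L,
    sex = sex, age_value = age_value, age_unit = age_unit,
    country = country
  )
  drug_tab <- tibble::tibble(report_id = report_id[mention[, 1]],
                             drug_name = verbatim)
  reac_tab <- dplyr::bind_rows(lapply(seq_along(pts), function(k) {
    tibble::tibble(report_id = report_id[reac_rows[[k]]], pt = pts[k])
  }))
  if (nrow(reac_tab) == 0) {
    reac_tab <- tibble::tibble(report_id = character(), pt = character())
  }

  if (config$duplicate_case_prob > 0) {
    dup <- stats::runif(n) < config$duplicate_case_prob
    if (any(dup)) {
      ids <- which(dup)
      old_id <- paste0(case_id[ids], "-1")
      demo <- dplyr::bind_rows(demo, dplyr::mutate(
        demo[ids, ], report_id = old_id, version = 1L))
      idx <- match(drug_tab$report_id, report_id[ids])
      dup_drugs <- drug_tab[!is.na(idx), ]
      dup_drugs$report_id <- old_id[idx[!is.na(idx)]]
      drug_tab <- dplyr::bind_rows(drug_tab, dup_drugs)
      ridx <- match(reac_tab$report_id, report_id[ids])
      dup_reac <- reac_tab[!is.na(ridx), ]
      if (nrow(dup_reac) > 0) {
        dup_reac$report_id <- old_id[ridx[!is.na(ridx)]]
        reac_tab <- dplyr::bind_rows(reac_tab, dup_reac)
      }
    }
  }

  report_set(demo, drug_tab, reac_tab,
             provenance = sprintf("synthetic (seed %d)", config$seed))
}

#' Expected PRR of a (drug, PT) pair under a synthetic configuration
#'
#' Closed-form expectation of the PRR the pipeline estimates, computed from
#' the generator's joint probabilities: the per-report event probability is
#' `min(1, q * max(lambda of planted drugs present, 1))`, so conditioning
#' on the target drug's presence and enumerating the presence patterns of
#' the other planted drugs for that PT gives the exact ratio of conditional
#' event probabilities. For a single planted pair with rare background and
#' independent drugs this equals `lambda`; for unplanted drugs it is
#' exactly 1, since co-occurring planted drugs contaminate the target and
#' background arms at the same marginal rate. Assumes drug mentions
#' independent (the at-least-one-drug resampling is a negligible
#' perturbation at small marginals).
#'
#' @param config A [synthetic_config()].
#' @param drug Canonical drugname in the config's vocabulary.
#' @param pt A PT in the config's catalog.
#' @return The expected PRR (ratio of event probability given the drug to
#'   event probability given its absence).
#' @export
expected_prr <- function(config, drug, pt) {
  stopifnot(inherits(config, "synthetic_config"))
  if (!drug %in% config$vocab$entries$canonical) {
    stop("unknown drug: ", drug, call. = FALSE)
  }
  if (!pt %in% config$pt_catalog) stop("unknown PT: ", pt, call. = FALSE)
  q <- config$background_event_prob[[pt]]
  if (q == 0) stop("zero background probability: expected PRR undefined",
                   call. = FALSE)
  pl <- config$planted[config$planted$pt == pt, ]
  lambda_self <- if (drug %in% pl$drug) pl$lambda[pl$drug == drug][1] else
    NULL
  others <- pl[pl$drug != drug, ]

  # E[min(1, q * mult)] with mult = max lambda among present planted drugs
  # (1 when none), enumerating presence patterns of the other planted drugs
  cond_event_prob <- function(self_lambda) {
    k <- nrow(others)
    masks <- if (k == 0) list(logical(0)) else
      lapply(0:(2^k - 1),
             function(mask) bitwAnd(mask, 2^(seq_len(k) - 1)) > 0)
    total <- 0
    for (bits in masks) {
      pr <- if (length(bits) == 0) 1 else
        prod(ifelse(bits, config$drug_marginals[others$drug],
                    1 - config$drug_marginals[others$drug]))
      lams <- c(self_lambda, others$lambda[bits])
      mult <- if (length(lams) == 0) 1 else max(lams)
      total <- total + pr * min(1, q * mult)
    }
    total
  }
  cond_event_prob(lambda_self) / cond_event_prob(NULL)
}
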