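# deterministic report set with one engineered association: furosemide
# reports are gout-enriched, everything else at background
planted_rs <- function() {
  n <- 400
  ids <- sprintf("R%04d", seq_len(n))
  # 100 furosemide reports (40 with gout), 100 metoprolol (2 with gout),
  # 200 background aspirin reports (4 with gout)
  drug <- c(rep("Lasix", 100), rep("Lopressor", 100), rep("aspirin", 200))
  gout <- c(rep(TRUE, 40), rep(FALSE, 60),
            rep(TRUE, 2), rep(FALSE, 98),
            rep(TRUE, 4), rep(FALSE, 196))
  demo <- tibble::tibble(report_id = ids, case_id = ids, version = 1L,
                         sex = "male", age_value = NA_real_,
                         age_unit = NA_character_, country = NA_character_)
  drugs <- tibble::tibble(report_id = ids, drug_name = drug)
  reac <- tibble::tibble(report_id = ids[gout],
                         pt = rep("Gout", sum(gout)))
  report_set(demo, drugs, reac)
}

test_that("screening flags exactly the engineered association", {
  rs <- planted_rs()
  v <- tiny_vocab()
  evs <- list(gout_event())
  res <- run_screen(rs, v, evs)
  df <- res$per_event[["gout"]]
  expect_equal(nrow(df), 3)  # every vocabulary drug appears exactly once
  expect_equal(df$positive, df$drug == "furosemide")
  # verify the flagged pair against hand-computed cells
  fur <- df[df$drug == "furosemide", ]
  expect_equal(c(fur$a, fur$b, fur$c, fur$d), c(40, 60, 6, 294))
  expect_equal(fur$prr, (40 / 100) / (6 / 300))
  expect_identical(names(res$overlap), "furosemide")
})

test_that("pairs with undefined statistics are kept with reason codes", {
  rs <- planted_rs()
  v <- tiny_vocab()
  # an event no report carries
  res <- run_screen(rs, v, list(event_definition("tophus", "Gouty tophus")))
  df <- res$per_event[["tophus"]]
  expect_true(all(!df$positive))
  # drugs present in reports but no cases anywhere
  expect_equal(df$reason[df$drug == "furosemide"], "no cases")
  expect_equal(df$prr[df$drug == "furosemide"], 0)
  # Hyzaar never appears in the fixture at all
  expect_equal(
    df$reason[df$drug ==
                "Hyzaar (losartan potassium and hydrochlorothiazide)"],
    "drug not reported")
})

test_that("drugs with identical report membership get identical results", {
  n <- 100
  ids <- sprintf("R%03d", seq_len(n))
  demo <- tibble::tibble(report_id = ids, case_id = ids, version = 1L,
                         sex = "male", age_value = NA_real_,
                         age_unit = NA_character_, country = NA_character_)
  # every report mentions both drugs
  drugs <- tibble::tibble(report_id = rep(ids, 2),
                          drug_name = rep(c("Lasix", "Lopressor"), each = n))
  reac <- tibble::tibble(report_id = ids[1:10], pt = "Gout")
  rs <- report_set(demo, drugs, reac)
  res <- run_screen(rs, tiny_vocab(), list(gout_event()))
  df <- res$per_event[["gout"]]
  cols <- c("a", "b", "c", "d", "prr", "chi2", "positive")
  expect_equal(df[df$drug == "furosemide", cols],
               df[df$drug == "metoprolol", cols])
})

test_that("screen output is invariant to report order", {
  rs <- random_report_set(120, seed = 9)
  set.seed(1)
  perm <- sample(n_reports(rs))
  rs_perm <- report_set(
    rs$demo[perm, setdiff(names(rs$demo), "age_years")],
    rs$drugs[sample(nrow(rs$drugs)), ],
    rs$reactions, provenance = rs$provenance)
  v <- tiny_vocab()
  evs <- list(gout_event())
  a <- run_screen(rs, v, evs)$per_event[["gout"]]
  b <- run_screen(rs_perm, v, evs)$per_event[["gout"]]
  expect_equal(a, b)
})

test_that("positive counts and overlap are internally consistent", {
  tabs <- published_signal_tables()
  res <- screen_result_from_tables(tabs)
  oh <- overlap_histogram(res)
  # every drug with >=1 positive lands in exactly one histogram bucket
  expect_equal(sum(oh$histogram$n_drugs), oh$n_ge1)
  expect_equal(sum(oh$histogram$n_drugs[oh$histogram$n_events >= 2]),
               oh$n_ge2)
  expect_setequal(names(res$overlap),
                  unlist(oh$histogram$drugs))
  # count_positive agrees with the positives-only grouped view
  v <- example_vocab()
  for (lab in names(tabs)) {
    expect_equal(count_positive(res, lab),
                 sum(res$per_event[[lab]]$positive))
  }
  expect_error(count_positive(res, "not screened"), "not screened")
})

test_that("single-event screens produce a single-key histogram", {
  rs <- planted_rs()
  res <- run_screen(rs, tiny_vocab(), list(gout_event()))
  oh <- overlap_histogram(res)
  expect_equal(nrow(oh$histogram), 1)
  expect_equal(oh$histogram$n_events, 1L)
  expect_equal(oh$n_ge2, 0L)
})

test_that("grouped rows follow the fixed class order, then vocabulary order", {
  rs <- planted_rs()
  v <- tiny_vocab()
  res <- run_screen(rs, v, list(gout_event()))
  all_rows <- group_by_class(res, v, "gout", positives_only = FALSE)
  expect_equal(nrow(all_rows), nrow(v$entries))
  expect_equal(all_rows$drug_class,
               c("Diuretics", "Beta blockers", "Compound preparations"))
  pos_rows <- group_by_class(res, v, "gout", positives_only = TRUE)
  expect_equal(nrow(pos_rows), count_positive(res, "gout"))
  expect_true(all(pos_rows$positive))
  expect_error(group_by_class(res, v, "nope"), "not screened")
})

test_that("grouped published rows reproduce the printed table layout", {
  tabs <- published_signal_tables()
  res <- screen_result_from_tables(tabs)
  # a vocabulary carrying the published class order and row order
  tt <- tabs[["gouty tophus"]]
  p <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(
    class_order = unique(tt$drug_class),
    drugs = lapply(seq_len(nrow(tt)), function(i)
      list(canonical = tt$drug_name[i], class = tt$drug_class[i]))
  ), p)
  v <- load_vocabulary(p)
  rows <- group_by_class(res, v, "gouty tophus", positives_only = TRUE)
  expect_equal(nrow(rows), 8)
  expect_equal(length(unique(rows$drug_class)), 5)
  expect_equal(rows$drug, tt$drug_name)
})

test_that("overlap table serializes one row per multi-signal drug", {
  res <- screen_result_from_tables(published_signal_tables())
  path <- tempfile(fileext = ".csv")
  write_overlap_table(res, path)
  out <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(nrow(out), overlap_histogram(res)$n_ge1)
  expect_equal(sum(out$n_positive_events >= 2),
               overlap_histogram(res)$n_ge2)
  fur <- out[out$drug == "Furosemide", ]
  expect_equal(fur$n_positive_events, 5L)
})
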