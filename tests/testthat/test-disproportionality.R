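make_rs <- function(drug_flags, event_flags) {
  n <- length(drug_flags)
  ids <- sprintf("R%03d", seq_len(n))
  demo <- tibble::tibble(report_id = ids, case_id = ids, version = 1L,
                         sex = "male", age_value = NA_real_,
                         age_unit = NA_character_, country = NA_character_)
  drugs <- tibble::tibble(
    report_id = ids,
    drug_name = ifelse(drug_flags, "Lasix", "aspirin")
  )
  reac <- tibble::tibble(report_id = ids[event_flags],
                         pt = rep("Gout", sum(event_flags)))
  report_set(demo, drugs, reac)
}

test_that("contingency cells count reports by drug x event membership", {
  # 10 reports: 2 drug+event, 3 drug only, 1 event only, 4 neither
  rs <- make_rs(drug_flags = c(rep(TRUE, 5), rep(FALSE, 5)),
                event_flags = c(TRUE, TRUE, FALSE, FALSE, FALSE,
                                TRUE, FALSE, FALSE, FALSE, FALSE))
  tab <- build_contingency(rs, tiny_vocab(), "furosemide", gout_event())
  expect_equal(unlist(tab), c(a = 2, b = 3, c = 1, d = 4))
  expect_equal(tab$a + tab$b + tab$c + tab$d, n_reports(rs))
})

test_that("a drug absent from all reports gives an empty drug row", {
  rs <- make_rs(drug_flags = rep(FALSE, 6),
                event_flags = c(TRUE, rep(FALSE, 5)))
  tab <- build_contingency(rs, tiny_vocab(), "furosemide", gout_event())
  expect_equal(tab$a, 0)
  expect_equal(tab$b, 0)
  expect_equal(tab$c + tab$d, 6)
})

test_that("contingency construction matches a brute-force per-report recount", {
  v <- tiny_vocab()
  ev <- gout_event()
  for (seed in c(101, 202)) {
    rs <- random_report_set(200, seed = seed)
    tab <- build_contingency(rs, v, "furosemide", ev)
    # oracle: classify each report independently through the single-report
    # predicates
    cells <- c(a = 0, b = 0, c = 0, d = 0)
    for (id in rs$demo$report_id) {
      hd <- report_has_drug(rs, v, id, "furosemide")
      he <- report_has_event(rs, ev, id)
      cell <- if (hd && he) "a" else if (hd) "b" else if (he) "c" else "d"
      cells[cell] <- cells[cell] + 1
    }
    expect_equal(unlist(tab), cells)
  }
})

test_that("empty report sets have no background to screen against", {
  demo <- tibble::tibble(report_id = character(), case_id = character(),
                         version = integer(), sex = character(),
                         age_value = numeric(), age_unit = character(),
                         country = character())
  rs <- report_set(demo,
                   tibble::tibble(report_id = character(),
                                  drug_name = character()),
                   tibble::tibble(report_id = character(), pt = character()))
  expect_error(build_contingency(rs, tiny_vocab(), "furosemide",
                                 gout_event()), "empty")
})

test_that("PRR is the ratio of event frequencies, with exact edge values", {
  expect_equal(compute_prr(contingency_table(10, 90, 10, 90)), 1.0)
  # event twice as frequent with the drug (4% vs 2%)
  expect_equal(compute_prr(contingency_table(4, 96, 2, 98)), 2.0)
  # 5% against 1%
  expect_equal(compute_prr(contingency_table(5, 95, 100, 9900)), 5.0)
  expect_equal(compute_prr(contingency_table(0, 50, 10, 90)), 0)
  expect_equal(compute_prr(contingency_table(3, 50, 0, 90)), Inf)
  expect_error(compute_prr(contingency_table(0, 0, 10, 90)), "PRR undefined")
  expect_error(compute_prr(contingency_table(5, 95, 0, 0)), "undefined")
})

test_that("Haldane continuity keeps zero-cell PRRs finite", {
  t0 <- contingency_table(3, 50, 0, 90)
  expect_equal(compute_prr(t0, continuity = 0.5),
               (3.5 / 54) / (0.5 / 91))
  # no-op on tables without zero cells only in the limit; value shifts
  expect_lt(compute_prr(contingency_table(4, 96, 2, 98), continuity = 0.5),
            2.0)
})

test_that("PRR is non-decreasing in the a cell with b, c, d fixed", {
  prrs <- vapply(0:20, function(a)
    compute_prr(contingency_table(a, 80, 10, 890)), 0)
  expect_true(all(diff(prrs) >= 0))
})

test_that("chi-squared matches its closed form and symmetries", {
  # proportional rows -> exact independence
  expect_equal(compute_chi2(contingency_table(10, 90, 20, 180),
                            yates = FALSE), 0)
  # frozen closed-form value: 1100 * 10000^2 / (100*1000*120*980)
  expect_equal(compute_chi2(contingency_table(20, 80, 100, 900),
                            yates = FALSE), 9.35374149659864,
               tolerance = 1e-12)
  # transposing the table leaves the statistic unchanged
  for (y in c(TRUE, FALSE)) {
    expect_equal(compute_chi2(contingency_table(7, 13, 21, 59), yates = y),
                 compute_chi2(contingency_table(7, 21, 13, 59), yates = y))
    # swapping rows likewise
    expect_equal(compute_chi2(contingency_table(7, 13, 21, 59), yates = y),
                 compute_chi2(contingency_table(21, 59, 7, 13), yates = y))
  }
  expect_error(compute_chi2(contingency_table(0, 0, 10, 90)), "marginal")
})

test_that("Yates correction shrinks the statistic and floors at zero", {
  t <- contingency_table(20, 80, 100, 900)
  expect_lt(compute_chi2(t, yates = TRUE), compute_chi2(t, yates = FALSE))
  # |ad - bc| = 5 <= n/2 = 75.5: corrected statistic floors at exactly 0
  t_small <- contingency_table(5, 45, 10, 91)
  expect_gt(compute_chi2(t_small, yates = FALSE), 0)
  expect_equal(compute_chi2(t_small, yates = TRUE), 0)
})

test_that("chi-squared agrees with independent oracles on random tables", {
  set.seed(42)
  for (i in 1:1000) {
    cells <- rpois(4, lambda = sample(c(2, 10, 50), 1)) + 1
    t <- contingency_table(cells[1], cells[2], cells[3], cells[4])
    m <- matrix(cells, 2, 2, byrow = TRUE)
    # cell-wise sum (O-E)^2/E
    E <- outer(rowSums(m), colSums(m)) / sum(m)
    expect_equal(compute_chi2(t, yates = FALSE), sum((m - E)^2 / E),
                 tolerance = 1e-9)
  }
  # stats::chisq.test as a second, library-independent route (both variants)
  set.seed(43)
  for (i in 1:50) {
    cells <- rpois(4, 20) + 1
    t <- contingency_table(cells[1], cells[2], cells[3], cells[4])
    m <- matrix(cells, 2, 2, byrow = TRUE)
    expect_equal(compute_chi2(t, yates = FALSE),
                 unname(chisq.test(m, correct = FALSE)$statistic),
                 tolerance = 1e-12)
    expect_equal(compute_chi2(t, yates = TRUE),
                 unname(chisq.test(m, correct = TRUE)$statistic),
                 tolerance = 1e-12)
  }
})

test_that("the Evans rule is an inclusive three-way conjunction", {
  # boundary grid crossing each threshold
  grid <- expand.grid(n = c(2, 3, 4), prr = c(1.99, 2, 2.01),
                      chi2 = c(3.99, 4, 4.01))
  got <- classify_signal(grid$n, grid$prr, grid$chi2)
  expect_equal(got, grid$n >= 3 & grid$prr >= 2 & grid$chi2 >= 4)
  # exact-boundary case is positive; high-statistic two-case pair is not
  expect_true(classify_signal(3, 2.0, 4.0))
  expect_false(classify_signal(2, 10.0, 50.0))
  expect_false(classify_signal(5, 1.99, 30.0))
  # infinite PRR satisfies the PRR arm; NA statistics never classify
  expect_true(classify_signal(5, Inf, 10))
  expect_false(classify_signal(5, 3, NA))
})
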