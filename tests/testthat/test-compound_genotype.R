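aln <- read_alignment()

test_that("compound status partitions subjects and flags incompleteness", {
  sub <- make_subjects(
    rep("case", 5),
    B_1 = c("B*57:01", "B*57:01", "B*07:02", "B*07:02", NA),
    B_2 = c("B*35:01", "B*35:01", "B*35:01", "B*35:01", "B*07:02"),
    kir3ds1 = c(TRUE, FALSE, TRUE, FALSE, TRUE)
  )
  st <- compound_status(cohort_table(sub), aln)
  expect_equal(unname(st),
               c("both", "bw4_only", "kir_only", "neither", "incomplete"))

  # missing KIR flag is incomplete even with full HLA-B typing
  sub$kir3ds1[1] <- NA
  st2 <- compound_status(cohort_table(sub), aln)
  expect_equal(unname(st2[1]), "incomplete")

  # the four complete categories account for every complete subject
  fx <- table6_fixture(aln)
  st3 <- compound_status(fx, aln)
  complete <- sum(st3 != "incomplete")
  expect_equal(sum(table(st3)[c("both", "kir_only", "bw4_only", "neither")]),
               complete)
  expect_equal(complete, 331 + 245)
})

test_that("odds ratios follow the cross product with principled edge
           handling", {
  expect_equal(odds_ratio(contingency_2x2(10, 10, 10, 10))$or, 1.0)
  expect_equal(odds_ratio(contingency_2x2(3, 2, 1, 4))$or, 6.0)

  expect_warning(res <- odds_ratio(contingency_2x2(5, 0, 2, 3)), "Haldane")
  expect_true(is.finite(res$or))
  expect_error(odds_ratio(contingency_2x2(0, 10, 0, 10)), "zero margin")
  expect_error(contingency_2x2(-1, 2, 3, 4), "nonnegative")

  # equivariance: swapping exposure or phenotype labels inverts the OR
  set.seed(31)
  for (i in 1:20) {
    cells <- rpois(4, 20) + 1
    or0 <- odds_ratio(do.call(contingency_2x2, as.list(cells)))$or
    swap_exp <- odds_ratio(contingency_2x2(cells[2], cells[1],
                                           cells[4], cells[3]))$or
    swap_ph <- odds_ratio(contingency_2x2(cells[3], cells[4],
                                          cells[1], cells[2]))$or
    expect_equal(swap_exp, 1 / or0, tolerance = 1e-12)
    expect_equal(swap_ph, 1 / or0, tolerance = 1e-12)
  }
})

test_that("the exact test matches enumeration and known closed forms", {
  expect_equal(fisher_exact(contingency_2x2(10, 10, 10, 10)), 1.0)
  expect_equal(fisher_exact(contingency_2x2(5, 0, 0, 5)),
               2 / choose(10, 5), tolerance = 1e-12)

  # random tables against the enumeration oracle and stats::fisher.test
  set.seed(17)
  for (i in 1:50) {
    cells <- rpois(4, 8)
    p_pkg <- fisher_exact(do.call(contingency_2x2, as.list(cells)))
    p_oracle <- oracle_fisher_two_sided(cells[1], cells[2],
                                        cells[3], cells[4])
    expect_equal(p_pkg, p_oracle, tolerance = 1e-10)
    p_ref <- fisher.test(matrix(cells, 2, byrow = TRUE))$p.value
    expect_equal(p_pkg, p_ref, tolerance = 1e-6)
  }

  # one-sided alternatives are hypergeometric tails
  tab <- contingency_2x2(8, 2, 3, 7)
  expect_equal(fisher_exact(tab, "greater") + fisher_exact(tab, "less"),
               1 + dhyper(8, 11, 9, 10), tolerance = 1e-12)
})

test_that("carrier tables exclude incomplete subjects per analysis", {
  fx <- table6_fixture(aln)
  tab <- suppressMessages(carrier_table(fx, predicate_compound(aln, "both")))
  expect_equal(attr(tab, "n_excluded"), 679L - 331L - 245L)

  # single-marker denominators differ from the compound ones
  tab_kir <- suppressMessages(carrier_table(fx, predicate_kir3ds1()))
  expect_equal(tab_kir$a + tab_kir$b, 397)
  tab_bw4 <- suppressMessages(carrier_table(fx, predicate_bw4_80i(aln)))
  expect_equal(tab_bw4$a + tab_bw4$b, 339)

  # an always-false predicate: OR undefined, exact p = 1
  tab0 <- carrier_table(fx, function(s) FALSE)
  expect_equal(tab0$a + tab0$c, 0)
  expect_error(odds_ratio(tab0), "zero margin")
  expect_equal(fisher_exact(tab0), 1.0)
})

test_that("logistic carrier fits reproduce contingency odds ratios", {
  set.seed(53)
  for (i in 1:10) {
    cells <- rpois(4, 30) + 5
    tab <- do.call(contingency_2x2, as.list(cells))
    or_tab <- odds_ratio(tab)$or
    y <- rep(c(1, 1, 0, 0), cells)
    x <- rep(c(1, 0, 1, 0), cells)
    or_fit <- fit_logistic(y, x)$or_
    expect_equal(or_fit, or_tab, tolerance = 1e-7)
  }
})
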