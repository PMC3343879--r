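test_that("cohort files round-trip through read and write", {
  sub <- make_subjects(
    c("case", "control", "control"),
    A_1 = c("A*01:01", "A*02:01", NA),
    A_2 = c("A*01:01", "A*03:01", "A*02:01"),
    B_1 = c("B*57:01", "B*07:02", "B*08:01"),
    B_2 = c("B*27:05", "B*07:02", NA),
    kir3ds1 = c(TRUE, FALSE, NA)
  )
  sub$pc1 <- c(0.1, -0.2, 0.05)
  co <- cohort_table(sub)
  expect_equal(nrow(co$subjects), 3L)
  expect_equal(n_cases(co), 1L)

  path <- tempfile(fileext = ".tsv")
  write_cohort(co, path)
  co2 <- read_cohort(path)
  expect_equal(co2$subjects, co$subjects)
  expect_equal(co2$loci, co$loci)

  # second round trip is byte-identical
  path2 <- tempfile(fileext = ".tsv")
  write_cohort(co2, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("malformed alleles and duplicate ids are rejected with context", {
  sub <- make_subjects(c("case", "control"),
                       B_1 = c("B*57:01", "B*5701"),
                       B_2 = c("B*27:05", "B*07:02"))
  expect_error(cohort_table(sub), "row 2.*B\\*5701")

  sub2 <- make_subjects(c("case", "control"),
                        B_1 = c("B*57:01", "B*07:02"),
                        B_2 = c("B*27:05", "B*07:02"))
  sub2$id <- c("x", "x")
  expect_error(cohort_table(sub2), "duplicate subject id")

  # locus encoded in the name must match the column's locus
  sub3 <- make_subjects("case", B_1 = "C*06:02", B_2 = "B*07:02")
  expect_error(cohort_table(sub3), "malformed|locus")
})

test_that("two-digit calls are recognised and recorded", {
  p <- parse_allele(c("C*06", "B*57:01", NA))
  expect_equal(p$resolution, c("two_digit", "four_digit", NA))
  expect_equal(p$locus, c("C", "B", NA))
  expect_true(p$missing[3])

  sub <- make_subjects("case", C_1 = "C*06", C_2 = "C*07")
  co <- cohort_table(sub)
  expect_equal(co$subjects$C_1, "C*06")

  # collapsing a four-digit cohort truncates at the first colon
  sub4 <- make_subjects(c("case", "control"),
                        C_1 = c("C*06:02", "C*07:01"),
                        C_2 = c("C*06:02", "C*07:02"))
  co2 <- collapse_two_digit(cohort_table(sub4))
  expect_equal(sort(unique(unlist(co2$subjects[c("C_1", "C_2")]))),
               c("C*06", "C*07"))
})

test_that("allele frequencies use non-missing chromosomes and sum to one", {
  # one subject homozygous B*57:01 -> frequency 1 at locus B
  solo <- cohort_table(make_subjects(c("case", "control"),
                                     B_1 = c("B*57:01", NA),
                                     B_2 = c("B*57:01", NA)))
  f <- suppressMessages(allele_frequencies(solo, "cases"))
  expect_equal(f$freq[f$allele == "B*57:01"], 1.0)

  # estimate within 3 binomial SEs of the truth at n = 2000
  set.seed(11)
  n <- 2000
  draw <- function() sample(c("A*01:01", "A*02:01"), n, replace = TRUE,
                            prob = c(0.10, 0.90))
  co <- cohort_table(make_subjects(rep(c("case", "control"), n / 2),
                                   A_1 = draw(), A_2 = draw()))
  f <- allele_frequencies(co, "all")
  se <- sqrt(0.1 * 0.9 / (2 * n))
  expect_lt(abs(f$freq[f$allele == "A*01:01"] - 0.10), 3 * se)

  # sums to 1 within 1e-12 per locus and group, with missingness present
  ch <- generate_cohort(simulation_spec(n_cases = 150, n_controls = 300,
                                        missing_rate = 0.1, seed = 5))
  for (grp in c("all", "cases", "controls")) {
    f <- suppressMessages(allele_frequencies(ch, grp))
    sums <- tapply(f$freq, f$locus, sum)
    expect_true(all(abs(sums - 1) < 1e-12))
  }
})

test_that("the MAF filter is strict and depends only on controls", {
  # 1000 control chromosomes: 9 copies = 0.9% -> excluded at 1%
  rare <- c(rep("A*01:01", 9), rep("A*02:01", 991))
  cases <- rep(c("A*01:01", "A*02:01"), c(50, 950))  # 5% in cases
  sub <- make_subjects(rep(c("case", "control"), each = 500),
                       A_1 = c(cases[1:500], rare[1:500]),
                       A_2 = c(cases[501:1000], rare[501:1000]))
  co <- cohort_table(sub)
  kept <- maf_filter_cohort(co, 0.01)
  expect_false("A*01:01" %in% kept)
  expect_true("A*02:01" %in% kept)

  # exactly 1.0% in controls -> excluded (strict inequality)
  exact <- c(rep("A*01:01", 10), rep("A*02:01", 990))
  sub2 <- sub
  sub2$A_1[501:1000] <- exact[1:500]
  sub2$A_2[501:1000] <- exact[501:1000]
  kept2 <- maf_filter_cohort(cohort_table(sub2), 0.01)
  expect_false("A*01:01" %in% kept2)

  # permuting case genotypes never changes the filter
  sub3 <- sub
  set.seed(2)
  perm <- sample(1:500)
  sub3$A_1[1:500] <- sub$A_1[perm]
  sub3$A_2[1:500] <- sub$A_2[perm]
  expect_equal(maf_filter_cohort(cohort_table(sub3), 0.01), kept)

  expect_error(maf_filter(data.frame(allele = "x", freq = 0.5), 0.6),
               "threshold")
})
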