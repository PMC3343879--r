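aln <- read_alignment()

test_that("Bw4/Bw6 classification follows the position-80 rule", {
  expect_equal(classify_bw("B*57:01", aln), "Bw4_80I")
  expect_equal(classify_bw("B*27:05", aln), "Bw4_80T")
  expect_equal(classify_bw(c("B*35:01", "B*40:01"), aln), c("Bw6", "Bw6"))
  # total and pure: unknown allele and missing call classify as unknown,
  # and repeated evaluation yields the same class
  expect_equal(classify_bw("B*99:99", aln), "unknown")
  expect_equal(classify_bw(NA_character_, aln), "unknown")
  expect_equal(classify_bw("B*57:01", aln), classify_bw("B*57:01", aln))
  expect_error(classify_bw("C*06:02", aln), "locus B")
})

test_that("residue expansion gives additive dosages that conserve to 2", {
  hom <- cohort_table(make_subjects(c("case", "control", "control"),
                                    B_1 = c("B*57:01", "B*07:02", "B*57:01"),
                                    B_2 = c("B*57:01", "B*07:02", "B*07:02")))
  m <- expand_residues(hom, aln, min_control_freq = 0)
  expect_equal(unname(marker_residue(m, "B", 80, "I")), c(2, 0, 1))

  # row conservation on a generated cohort: per position, dosages sum to 2
  ch <- generate_cohort(simulation_spec(n_cases = 120, n_controls = 240,
                                        seed = 9))
  m2 <- expand_residues(ch, aln, min_control_freq = 0)
  for (loc in unique(m2$columns$locus)) {
    for (pos in unique(m2$columns$position[m2$columns$locus == loc])) {
      ids <- m2$columns$id[m2$columns$locus == loc &
                             m2$columns$position == pos]
      sums <- rowSums(m2$dosage[, ids, drop = FALSE])
      expect_true(all(sums[!is.na(sums)] == 2))
    }
  }

  # a cohort restricted to one allele is 2 x the allele's residue indicator
  only <- cohort_table(make_subjects(c("case", "control"),
                                     B_1 = "B*57:01", B_2 = "B*57:01"))
  m3 <- expand_residues(only, aln, min_control_freq = 0)
  expect_true(all(m3$dosage == 2))
})

test_that("gap-coded alleles contribute only their non-gap partner", {
  tiny <- make_alignment(
    c("B*01:01", "B*02:02"), c(10, 20),
    matrix(c("A", "-",
             "S", "T"), 2, byrow = TRUE)
  )
  co <- cohort_table(make_subjects(c("case", "control", "control"),
                                   B_1 = c("B*01:01", "B*02:02", "B*01:01"),
                                   B_2 = c("B*02:02", "B*02:02", "B*01:01")))
  m <- expand_residues(co, tiny, min_control_freq = 0)
  # at position 20, B*01:01 is gap: the heterozygote counts only B*02:02
  expect_equal(unname(marker_residue(m, "B", 20, "T")), c(1, 2, NA))
  # at position 10 both alleles are defined
  expect_equal(unname(marker_residue(m, "B", 10, "A")), c(1, 0, 2))
})

test_that("residue frequency equals the sum of carrying-allele frequencies", {
  ch <- generate_cohort(simulation_spec(n_cases = 200, n_controls = 400,
                                        seed = 13))
  m <- expand_residues(ch, aln, min_control_freq = 0)
  af <- allele_frequencies(ch, "controls")
  bfreq <- af[af$locus == "B", ]
  carrying <- rownames(aln$B$residues)[
    aln$B$residues[, as.character(80)] == "I"
  ]
  expected <- sum(bfreq$freq[bfreq$allele %in% carrying])
  got <- unname(m$control_freq["B:80:I"])
  expect_equal(got, expected, tolerance = 1e-12)
})

test_that("named allele groups resolve with overlap protection", {
  groups <- read_allele_groups()
  expect_equal(allele_group("B*35:02", groups), "B35_Px")
  expect_equal(allele_group("B*35:03", groups), "B35_Px")
  expect_equal(allele_group("B*35:01", groups), "B35_PY")
  expect_true(is.na(allele_group("B*57:01", groups)))
  expect_error(allele_group("B*35:01", list(a = "B*35:01", b = "B*35:01")),
               "overlap")
})

test_that("marker extraction errors name the residues that are present", {
  co <- cohort_table(make_subjects(c("case", "control"),
                                   B_1 = c("B*07:02", "B*44:02"),
                                   B_2 = c("B*44:05", "B*07:02")))
  m <- expand_residues(co, aln, min_control_freq = 0)
  # 116Y present through B*07:02 / B*44:05
  expect_gt(sum(marker_residue(m, "B", 116, "Y")), 0)
  expect_error(marker_residue(m, "B", 116, "Z"), "residues present.*Y")
  # dosages at 116 conserve to 2 x complete subjects
  ids <- m$columns$id[m$columns$position == 116]
  expect_equal(sum(m$dosage[, ids]), 2 * nrow(co$subjects))
})
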