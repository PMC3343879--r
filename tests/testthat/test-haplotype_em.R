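fake_em <- function(loci, freq, n_chromosomes) {
  structure(list(loci = loci, freq = freq, n_chromosomes = n_chromosomes),
            class = "hla_em")
}

test_that("single-locus EM returns the allele frequencies exactly", {
  sub <- make_subjects(rep("control", 10),
                       B_1 = rep(c("B*07:02", "B*08:01"), 5),
                       B_2 = rep("B*07:02", 10))
  est <- em_haplotypes(cohort_table(sub), "B")
  af <- allele_frequencies(cohort_table(sub), "all")
  expect_equal(unname(est$freq["B*07:02"]),
               af$freq[af$allele == "B*07:02"], tolerance = 1e-12)
})

test_that("EM equals direct counting when phase is certain", {
  # all homozygous at both loci
  sub <- make_subjects(rep("control", 20),
                       A_1 = rep(c("A*01:01", "A*02:01"), c(12, 8)),
                       A_2 = rep(c("A*01:01", "A*02:01"), c(12, 8)),
                       B_1 = rep(c("B*07:02", "B*08:01"), c(12, 8)),
                       B_2 = rep(c("B*07:02", "B*08:01"), c(12, 8)))
  est <- em_haplotypes(cohort_table(sub), c("A", "B"))
  expect_equal(unname(est$freq["A*01:01|B*07:02"]), 0.6, tolerance = 1e-12)
  expect_equal(unname(est$freq["A*02:01|B*08:01"]), 0.4, tolerance = 1e-12)

  # no double-heterozygote: every subject's phase is implied
  sub2 <- make_subjects(rep("control", 12),
                        A_1 = c(rep("A*01:01", 6), rep("A*01:01", 6)),
                        A_2 = c(rep("A*02:01", 6), rep("A*01:01", 6)),
                        B_1 = rep("B*07:02", 12),
                        B_2 = rep("B*07:02", 12))
  est2 <- em_haplotypes(cohort_table(sub2), c("A", "B"))
  phase <- data.frame(A.h1 = sub2$A_1, A.h2 = sub2$A_2,
                      B.h1 = sub2$B_1, B.h2 = sub2$B_2)
  counted <- count_phased(phase, c("A", "B"))
  expect_equal(est2$freq[names(counted)], counted, tolerance = 1e-9)
})

test_that("EM solves the 50/50/10 double-heterozygote instance", {
  sub <- make_subjects(rep("control", 110),
    A_1 = c(rep("A*01:01", 50), rep("A*02:01", 50), rep("A*01:01", 10)),
    A_2 = c(rep("A*01:01", 50), rep("A*02:01", 50), rep("A*02:01", 10)),
    B_1 = c(rep("B*07:02", 50), rep("B*08:01", 50), rep("B*07:02", 10)),
    B_2 = c(rep("B*07:02", 50), rep("B*08:01", 50), rep("B*08:01", 10)))
  est <- em_haplotypes(cohort_table(sub), c("A", "B"))
  t_star <- oracle_em_grid(50, 50, 10)
  expect_equal(unname(est$freq["A*01:01|B*07:02"]), t_star,
               tolerance = 1e-6)
  expect_equal(unname(est$freq["A*02:01|B*08:01"]), t_star,
               tolerance = 1e-6)
  # log-likelihood is monotone over the trace
  expect_true(all(diff(est$loglik_trace) >= -1e-9))
})

test_that("EM is deterministic and invariant to subject order", {
  ch <- generate_cohort(simulation_spec(n_cases = 150, n_controls = 300,
                                        seed = 23))
  e1 <- suppressMessages(em_haplotypes(ch, c("B", "C"), group = "controls"))
  e2 <- suppressMessages(em_haplotypes(ch, c("B", "C"), group = "controls"))
  expect_identical(e1$freq, e2$freq)

  perm <- ch
  set.seed(99)
  perm$subjects <- perm$subjects[sample(nrow(perm$subjects)), ]
  e3 <- suppressMessages(em_haplotypes(perm, c("B", "C"), group = "controls"))
  expect_equal(e3$freq[names(e1$freq)], e1$freq, tolerance = 1e-9)
})

test_that("EM recovers generator truth on phased synthetic cohorts", {
  errs <- vapply(1:5, function(s) {
    ch <- generate_cohort(simulation_spec(n_cases = 400, n_controls = 1500,
                                          seed = 100 + s))
    truth <- attr(ch, "truth")
    ctrl <- ch$subjects$phenotype == "control"
    counted <- count_phased(truth$phase[ctrl, ], c("B", "C"))
    est <- em_haplotypes(ch, c("B", "C"), group = "controls")
    common <- union(names(counted), names(est$freq))
    f1 <- ifelse(is.na(counted[common]), 0, counted[common])
    f2 <- ifelse(is.na(est$freq[common]), 0, est$freq[common])
    max(abs(f1 - f2))
  }, numeric(1))
  expect_lt(max(errs), 0.01)

  expect_error(count_phased(data.frame(x = 1), "B"), "phase annotation")
  expect_error(em_haplotypes(
    cohort_table(make_subjects("case", B_1 = NA, B_2 = NA,
                               B = NULL)), character(0)), "locus")
})

test_that("haplotype case-control tests use counts, ORs and the exact
           fallback correctly", {
  est_eq_a <- fake_em("B", c("B*07:02|x" = 0.2, other = 0.8), 1000)
  est_eq_b <- fake_em("B", c("B*07:02|x" = 0.2, other = 0.8), 2000)
  res <- haplotype_case_control_test(est_eq_a, est_eq_b, "B*07:02|x")
  expect_equal(res$or, 1.0, tolerance = 1e-9)
  expect_gt(res$p, 0.9)

  # closed form: 0.12 vs 0.03 should give OR near (0.12/0.88)/(0.03/0.97)
  est_a <- fake_em("B", c(h = 0.12, other = 0.88), 3000)
  est_b <- fake_em("B", c(h = 0.03, other = 0.97), 6000)
  res2 <- haplotype_case_control_test(est_a, est_b, "h")
  closed <- (0.12 / 0.88) / (0.03 / 0.97)
  expect_lt(abs(res2$or - closed) / closed, 0.2)
  expect_equal(res2$method, "chisq")

  # zero cell in one group: exact path, finite p
  est_z <- fake_em("B", c(h = 0.01, other = 0.99), 400)
  est_0 <- fake_em("B", c(other = 1), 400)
  res3 <- haplotype_case_control_test(est_z, est_0, "h")
  expect_equal(res3$method, "fisher")
  expect_true(is.finite(res3$p))

  expect_error(haplotype_case_control_test(est_z, est_0, "absent"),
               "absent from both")
})

test_that("LD statistics follow the closed forms", {
  # independence
  ind <- outer(c(0.3, 0.7), c(0.4, 0.6))
  ld <- ld_pair(ind)
  expect_equal(ld$abs_d_prime, 0)
  expect_equal(ld$r2, 0)

  # complete association with equal allele frequencies: D' = 1, r2 = 1
  m <- matrix(c(0.3, 0, 0, 0.7), 2)
  ld2 <- ld_pair(m)
  expect_equal(ld2$abs_d_prime, 1)
  expect_equal(ld2$r2, 1)

  # one missing haplotype class, unequal frequencies: |D'| = 1, r2 < 1
  m3 <- matrix(c(0.2, 0, 0.3, 0.5), 2, byrow = TRUE)
  ld3 <- ld_pair(m3)
  expect_equal(ld3$abs_d_prime, 1, tolerance = 1e-12)
  expect_lt(ld3$r2, 1)
  # closed form for r2 (row margin 0.2, column margin 0.5)
  pA <- 0.2; pB <- 0.5
  D <- 0.2 - pA * pB
  expect_equal(ld3$r2, D^2 / (pA * (1 - pA) * pB * (1 - pB)),
               tolerance = 1e-12)

  expect_error(ld_pair(matrix(c(0.5, 0.5, 0, 0), 2)), "monomorphic")
})

test_that("EM recovers 5-haplotype pools within 0.02 at n = 2000", {
  pool <- data.frame(
    A = c("A*01:01", "A*01:01", "A*02:01", "A*02:01", "A*03:01"),
    B = c("B*07:02", "B*08:01", "B*07:02", "B*44:02", "B*44:02"),
    freq = c(0.35, 0.25, 0.2, 0.15, 0.05),
    stringsAsFactors = FALSE
  )
  errs <- vapply(1:5, function(s) {
    spec <- simulation_spec(loci = c("A", "B"), haplotypes = pool,
                            allele_effects = c("A*01:01" = 0.4),
                            kir_bw4_beta = 0, cohort_beta = 0,
                            pc_beta = numeric(0), cohort_pc_shift = 0,
                            n_cases = 500, n_controls = 2000, seed = 200 + s)
    ch <- generate_cohort(spec)
    truth <- attr(ch, "truth")
    ctrl <- ch$subjects$phenotype == "control"
    counted <- count_phased(truth$phase[ctrl, ], c("A", "B"))
    est <- em_haplotypes(ch, c("A", "B"), group = "controls")
    common <- union(names(counted), names(est$freq))
    f1 <- ifelse(is.na(counted[common]), 0, counted[common])
    f2 <- ifelse(is.na(est$freq[common]), 0, est$freq[common])
    max(abs(f1 - f2))
  }, numeric(1))
  expect_lt(max(errs), 0.02)
})
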