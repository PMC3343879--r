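# Synthetic case-control cohorts with the statistical structure the
# analyses assume: multi-locus haplotypes with strong LD drawn under HWE,
# logistic disease risk with allele / residue / interaction effects and
# covariate confounding, case-control ascertainment by rejection
# sampling, and a truth record (including phase) for every stage.

#' Default two-locus (HLA-B, HLA-C) haplotype pool
#'
#' A European-ancestry-like B-C haplotype pool with strong LD structure,
#' including a B*57:01-C*06:02 haplotype at base frequency 0.034 (the
#' control-population frequency reported for that haplotype) and common
#' Bw6 haplotypes such as B*07:02-C*07:02. Frequencies sum to 1.
#'
#' @return Data.frame with columns `B`, `C`, `freq`.
#' @export
default_haplotype_pool <- function() {
  pool <- utils::read.csv(text = "B,C,freq
B*57:01,C*06:02,0.034
B*13:02,C*06:02,0.024
B*37:01,C*06:02,0.013
B*38:01,C*12:03,0.022
B*18:01,C*07:01,0.022
B*44:03,C*16:01,0.029
B*07:02,C*07:02,0.112
B*40:01,C*03:04,0.048
B*27:05,C*01:02,0.012
B*18:01,C*12:03,0.019
B*35:01,C*04:01,0.050
B*08:01,C*07:01,0.080
B*44:02,C*05:01,0.090
B*15:01,C*03:04,0.060
B*51:01,C*14:02,0.050
B*35:02,C*04:01,0.012
B*35:03,C*04:01,0.015
B*40:02,C*02:02,0.020
B*55:01,C*03:03,0.016
B*39:01,C*12:03,0.012
B*14:02,C*08:02,0.030
B*50:01,C*06:02,0.030
B*49:01,C*07:01,0.030
B*45:01,C*16:01,0.020
B*53:01,C*04:01,0.020
B*56:01,C*01:02,0.020
B*40:01,C*02:02,0.030
B*15:01,C*03:03,0.080
", stringsAsFactors = FALSE)
  stopifnot(abs(sum(pool$freq) - 1) < 1e-9)
  pool
}

#' Specification of a synthetic case-control cohort
#'
#' Collects everything [generate_cohort()] needs: the haplotype pool, the
#' disease model and the sampling design. Defaults emulate the structure
#' of a large European psoriasis-style case-control study: 1727 cases and
#' 3581 controls drawn from a 2%-prevalence base population over two
#' cohorts with mild ancestry/cohort confounding, a leading HLA-C risk
#' allele with additional independent class I effects, an unlinked
#' KIR3DS1 locus at carrier frequency 0.33, and a positive
#' KIR3DS1 x Bw4-80I interaction.
#'
#' @param loci Ordered loci of the haplotype pool.
#' @param haplotypes Data.frame with one allele column per locus plus
#'   `freq` (summing to 1).
#' @param allele_effects Named numeric vector of per-allele log-odds
#'   (additive per dosage unit).
#' @param residue_effects Named numeric vector of residue effects with
#'   names `"locus:position:residue"` (requires `alignment`).
#' @param kir_freq KIR3DS1 carrier frequency (unlinked biallelic
#'   presence/absence locus).
#' @param kir_beta Log-odds of KIR3DS1 carriage.
#' @param kir_bw4_beta Log-odds of the KIR3DS1 x Bw4-80I compound
#'   genotype (dominant x dominant interaction; requires `alignment`).
#' @param deletion_map Optional `deletion_map` for planting a direct
#'   rs67384697 effect.
#' @param deletion_beta Log-odds per del allele (0 disables).
#' @param sex_beta,cohort_beta,pc_beta Covariate effects: `cohort_beta`
#'   one value per cohort (first is the reference), `pc_beta` one value
#'   per PC.
#' @param cohort_pc_shift Per-cohort mean shift of every PC (ancestry
#'   confounding).
#' @param n_cases,n_controls Target group sizes.
#' @param prevalence Disease prevalence at the linear-predictor baseline.
#' @param missing_rate Per-subject-per-locus probability that both calls
#'   are set missing (missing completely at random).
#' @param kir_missing_rate Probability that the KIR flag is missing.
#' @param alignment `protein_alignment` used for residue and Bw4 lookups
#'   (default: the packaged alignment when needed).
#' @param seed Default RNG seed for [generate_cohort()].
#' @return Object of class `simulation_spec`.
#' @export
simulation_spec <- function(loci = c("B", "C"),
                            haplotypes = default_haplotype_pool(),
                            allele_effects = c("C*06:02" = log(3.0),
                                               "B*57:01" = log(1.5),
                                               "B*27:05" = log(1.6),
                                               "B*35:01" = log(0.74),
                                               "B*35:02" = log(0.54),
                                               "B*35:03" = log(0.54)),
                            residue_effects = NULL,
                            kir_freq = 0.33,
                            kir_beta = 0,
                            kir_bw4_beta = log(3.9),
                            deletion_map = NULL,
                            deletion_beta = 0,
                            sex_beta = 0,
                            cohort_beta = c(0, log(1.2)),
                            pc_beta = c(0.1, 0.1),
                            cohort_pc_shift = c(0, 0.5),
                            n_cases = 1727,
                            n_controls = 3581,
                            prevalence = 0.02,
                            missing_rate = 0,
                            kir_missing_rate = 0,
                            alignment = NULL,
                            seed = 42) {
  stopifnot(is.data.frame(haplotypes), all(loci %in% names(haplotypes)),
            "freq" %in% names(haplotypes))
  if (abs(sum(haplotypes$freq) - 1) > 1e-8) {
    stop_fm("haplotype frequencies must sum to 1")
  }
  if (any(haplotypes$freq < 0)) stop_fm("haplotype frequencies must be >= 0")
  effs <- c(allele_effects, residue_effects, kir_beta, kir_bw4_beta,
            deletion_beta, sex_beta, cohort_beta, pc_beta)
  if (length(effs) && !all(is.finite(effs))) {
    stop_fm("all effect sizes must be finite")
  }
  if (n_cases < 1 || n_controls < 1) stop_fm("group sizes must be positive")
  if (!(prevalence > 0 && prevalence < 1)) {
    stop_fm("prevalence must be in (0, 1)")
  }
  structure(list(
    loci = loci, haplotypes = haplotypes,
    allele_effects = allele_effects, residue_effects = residue_effects,
    kir_freq = kir_freq, kir_beta = kir_beta, kir_bw4_beta = kir_bw4_beta,
    deletion_map = deletion_map, deletion_beta = deletion_beta,
    sex_beta = sex_beta, cohort_beta = cohort_beta, pc_beta = pc_beta,
    cohort_pc_shift = cohort_pc_shift,
    n_cases = n_cases, n_controls = n_controls, prevalence = prevalence,
    missing_rate = missing_rate, kir_missing_rate = kir_missing_rate,
    alignment = alignment, seed = seed
  ), class = "simulation_spec")
}

.needs_alignment <- function(spec) {
  (!is.null(spec$residue_effects) && length(spec$residue_effects)) ||
    spec$kir_bw4_beta != 0
}

#' Generate a synthetic case-control cohort with ground truth
#'
#' Per subject: two haplotypes are drawn from the pool under HWE,
#' covariates from the covariate model, and KIR3DS1 carriage
#' independently (an unlinked locus). Disease status follows a logistic
#' model on the additive allele/residue dosages, covariates, the KIR
#' effect and the dominant-model KIR x Bw4-80I interaction, with the
#' intercept set so the reference genotype has risk `prevalence`.
#' Case-control ascertainment is by rejection sampling from this base
#' population until both group sizes are met. Missingness is applied
#' last. The truth record retains the phased haplotypes and every planted
#' effect, sufficient to verify each downstream stage. Output is
#' byte-identical for identical spec and seed.
#'
#' @param spec A [simulation_spec()].
#' @param seed RNG seed (default: `spec$seed`).
#' @param max_batches Upper bound on rejection-sampling rounds before
#'   giving up (each round draws a multiple of the remaining need).
#' @return A [cohort_table()] with attribute `"truth"`: a list with
#'   `spec`, `phase` (data.frame of phased haplotypes, columns
#'   `"<locus>.h1"`/`"<locus>.h2"`), `kir3ds1`, and `deletion_dosage`
#'   when a deletion map was supplied.
#' @export
generate_cohort <- function(spec, seed = spec$seed, max_batches = 1000L) {
  stopifnot(inherits(spec, "simulation_spec"))
  alignment <- spec$alignment
  if (is.null(alignment) && .needs_alignment(spec)) {
    alignment <- read_alignment()
  }
  pool <- spec$haplotypes
  loci <- spec$loci
  n_hap <- nrow(pool)
  intercept <- stats::qlogis(spec$prevalence)
  n_cohorts <- length(spec$cohort_beta)
  n_pcs <- length(spec$pc_beta)

  bw4_carrier_of <- NULL
  if (!is.null(alignment) && "B" %in% loci) {
    cls <- classify_bw(pool$B, alignment)
    bw4_carrier_of <- cls == "Bw4_80I"
  }
  del_of <- NULL
  if (!is.null(spec$deletion_map) && "C" %in% loci) {
    m <- unclass(spec$deletion_map)
    del_of <- unname(m[pool$C]) == "del"
    del_of[is.na(del_of)] <- FALSE
  }

  draw_batch <- function(m) {
    h1 <- sample.int(n_hap, m, replace = TRUE, prob = pool$freq)
    h2 <- sample.int(n_hap, m, replace = TRUE, prob = pool$freq)
    cohort_id <- sample.int(n_cohorts, m, replace = TRUE)
    sex <- sample(c("F", "M"), m, replace = TRUE)
    pcs <- matrix(stats::rnorm(m * n_pcs), m, n_pcs)
    if (n_pcs) {
      pcs <- pcs + matrix(spec$cohort_pc_shift[cohort_id], m, n_pcs)
    }
    kir <- stats::runif(m) < spec$kir_freq

    eta <- rep(intercept, m)
    for (al in names(spec$allele_effects)) {
      loc <- allele_locus(al)
      if (!loc %in% loci) next
      dose <- (pool[[loc]][h1] == al) + (pool[[loc]][h2] == al)
      eta <- eta + spec$allele_effects[[al]] * dose
    }
    if (!is.null(spec$residue_effects)) {
      for (id in names(spec$residue_effects)) {
        parts <- strsplit(id, ":", fixed = TRUE)[[1]]
        loc <- parts[1]; pos <- as.integer(parts[2]); res <- parts[3]
        if (!loc %in% loci) next
        r_of <- vapply(pool[[loc]], alignment_residue,
                       character(1), alignment = alignment, position = pos)
        carries <- !is.na(r_of) & r_of == res
        dose <- carries[h1] + carries[h2]
        eta <- eta + spec$residue_effects[[id]] * dose
      }
    }
    eta <- eta + spec$kir_beta * kir
    bw4 <- NULL
    if (!is.null(bw4_carrier_of)) {
      bw4 <- bw4_carrier_of[h1] | bw4_carrier_of[h2]
      eta <- eta + spec$kir_bw4_beta * (kir & bw4)
    }
    del_dose <- NULL
    if (!is.null(del_of)) {
      del_dose <- del_of[h1] + del_of[h2]
      eta <- eta + spec$deletion_beta * del_dose
    }
    eta <- eta + spec$sex_beta * (sex == "M") +
      spec$cohort_beta[cohort_id]
    if (n_pcs) eta <- eta + as.vector(pcs %*% spec$pc_beta)
    y <- stats::runif(m) < stats::plogis(eta)
    list(h1 = h1, h2 = h2, cohort = cohort_id, sex = sex, pcs = pcs,
         kir = kir, del = del_dose, y = y)
  }

  with_seed(seed, {
    cases <- NULL; controls <- NULL
    got_cases <- 0L; got_controls <- 0L
    batches <- 0L
    take <- function(acc, b, idx, need) {
      idx <- utils::head(idx, need)
      sel <- lapply(b[c("h1", "h2", "cohort", "sex", "kir", "y")],
                    function(v) v[idx])
      sel$pcs <- b$pcs[idx, , drop = FALSE]
      sel$del <- if (!is.null(b$del)) b$del[idx]
      if (is.null(acc)) return(sel)
      out <- Map(function(a, v) {
        if (is.matrix(a)) rbind(a, v) else c(a, v)
      }, acc, sel)
      out
    }
    while (got_cases < spec$n_cases || got_controls < spec$n_controls) {
      batches <- batches + 1L
      if (batches > max_batches) {
        stop_fm("could not reach the requested case count after ",
                max_batches, " sampling rounds; check the effect model")
      }
      need_cases <- spec$n_cases - got_cases
      need_controls <- spec$n_controls - got_controls
      m <- as.integer(min(500000,
                          max(2000, 4 * max(need_cases / spec$prevalence,
                                            need_controls))))
      b <- draw_batch(m)
      if (need_cases > 0) {
        cases <- take(cases, b, which(b$y), need_cases)
        got_cases <- length(cases$h1)
      }
      if (need_controls > 0) {
        controls <- take(controls, b, which(!b$y), need_controls)
        got_controls <- length(controls$h1)
      }
    }
    all <- Map(function(a, v) {
      if (is.matrix(a)) rbind(a, v) else c(a, v)
    }, cases, controls)
    n <- length(all$h1)
    phenotype <- rep(c("case", "control"), c(spec$n_cases, spec$n_controls))
    ids <- sprintf("S%05d", seq_len(n))

    sub <- data.frame(id = ids, phenotype = phenotype,
                      sex = all$sex,
                      cohort = paste0("cohort", all$cohort),
                      stringsAsFactors = FALSE)
    if (n_pcs) {
      pcs <- all$pcs
      colnames(pcs) <- paste0("pc", seq_len(n_pcs))
      sub <- cbind(sub, pcs)
    }
    phase <- data.frame(id = ids, stringsAsFactors = FALSE)
    for (loc in loci) {
      a1 <- pool[[loc]][all$h1]
      a2 <- pool[[loc]][all$h2]
      phase[[paste0(loc, ".h1")]] <- a1
      phase[[paste0(loc, ".h2")]] <- a2
      if (spec$missing_rate > 0) {
        drop <- stats::runif(n) < spec$missing_rate
        a1[drop] <- NA; a2[drop] <- NA
      }
      sub[[paste0(loc, "_1")]] <- a1
      sub[[paste0(loc, "_2")]] <- a2
    }
    kir <- all$kir
    if (spec$kir_missing_rate > 0) {
      kir[stats::runif(n) < spec$kir_missing_rate] <- NA
    }
    sub$kir3ds1 <- kir
    cohort <- cohort_table(sub, loci = loci,
                           meta = list(source = "generate_cohort"))
    truth <- list(spec = spec, phase = phase, kir3ds1 = all$kir,
                  deletion_dosage = all$del, seed = seed)
    attr(cohort, "truth") <- truth
    cohort
  })
}

#' Deterministic KIR3DS1 / Bw4-80I demonstration cohort
#'
#' Builds a fixed cohort of 397 cases and 282 controls whose carrier
#' counts reproduce, cell for cell, a published KIR3DS1 x HLA-B Bw4-80I
#' carrier analysis, including the differing per-analysis denominators
#' that arise from planted missingness: KIR3DS1 is typed in everyone
#' (397/282), 339/247 subjects have at least one HLA-B call, and 331/245
#' have complete HLA-B typing, which the compound-genotype analyses
#' require. Carrier counts: compound genotype 75/331 cases vs 17/245
#' controls, KIR3DS1 185/397 vs 92/282, Bw4-80I 154/339 vs 58/247. The
#' construction is assertion-checked against every cell.
#'
#' @param alignment `protein_alignment` used for the build-time
#'   assertions (default: the packaged alignment).
#' @return A [cohort_table()] with loci `B` and a `kir3ds1` column.
#' @export
table6_fixture <- function(alignment = read_alignment()) {
  bw4 <- "B*57:01"   # Bw4-80I carrier genotype (with a Bw6 second allele)
  bw6 <- "B*07:02"
  other <- "B*35:01" # Bw6 partner allele
  block <- function(n, phenotype, kir, b1, b2) {
    if (n == 0L) return(NULL)
    data.frame(phenotype = phenotype, kir3ds1 = kir, B_1 = b1, B_2 = b2,
               stringsAsFactors = FALSE)[rep(1L, n), , drop = FALSE]
  }
  rows <- rbind(
    # cases: complete HLA-B (331)
    block(75L,  "case", TRUE,  bw4, other),   # both
    block(79L,  "case", TRUE,  bw6, other),   # kir_only
    block(76L,  "case", FALSE, bw4, other),   # bw4_only
    block(101L, "case", FALSE, bw6, other),   # neither
    # cases: one observed HLA-B call (8)
    block(2L, "case", TRUE,  bw4, NA), block(1L, "case", FALSE, bw4, NA),
    block(2L, "case", TRUE,  bw6, NA), block(3L, "case", FALSE, bw6, NA),
    # cases: no HLA-B calls (58)
    block(27L, "case", TRUE,  NA, NA), block(31L, "case", FALSE, NA, NA),
    # controls: complete HLA-B (245)
    block(17L,  "control", TRUE,  bw4, other),
    block(63L,  "control", TRUE,  bw6, other),
    block(40L,  "control", FALSE, bw4, other),
    block(125L, "control", FALSE, bw6, other),
    # controls: one observed HLA-B call (2)
    block(1L, "control", FALSE, bw4, NA), block(1L, "control", FALSE, bw6, NA),
    # controls: no HLA-B calls (35)
    block(12L, "control", TRUE, NA, NA), block(23L, "control", FALSE, NA, NA)
  )
  n <- nrow(rows)
  sub <- data.frame(
    id = sprintf("K%04d", seq_len(n)),
    phenotype = rows$phenotype,
    sex = rep(c("F", "M"), length.out = n),
    cohort = "kir_cohort",
    B_1 = rows$B_1, B_2 = rows$B_2,
    kir3ds1 = rows$kir3ds1,
    stringsAsFactors = FALSE
  )
  cohort <- cohort_table(sub, loci = "B",
                         meta = list(source = "table6_fixture"))
  # build-time assertion against every expected cell
  expect_cells <- list(
    list(predicate_compound(alignment, "both"), c(75, 256, 17, 228)),
    list(predicate_compound(alignment, "kir_only"), c(79, 252, 63, 182)),
    list(predicate_compound(alignment, "bw4_only"), c(76, 255, 40, 205)),
    list(predicate_kir3ds1(), c(185, 212, 92, 190)),
    list(predicate_bw4_80i(alignment), c(154, 185, 58, 189))
  )
  for (spec in expect_cells) {
    tab <- suppressMessages(carrier_table(cohort, spec[[1]]))
    got <- c(tab$a, tab$b, tab$c, tab$d)
    if (!identical(as.integer(got), as.integer(spec[[2]]))) {
      stop_fm("table6_fixture self-check failed: got ",
              paste(got, collapse = "/"), ", expected ",
              paste(spec[[2]], collapse = "/"))
    }
  }
  cohort
}
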