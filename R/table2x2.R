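#' 2x2 contingency table for carrier-level analyses
#'
#' Cell layout: `a` = exposed cases, `b` = unexposed cases, `c` = exposed
#' controls, `d` = unexposed controls (so `a + b` = cases, `c + d` =
#' controls).
#'
#' @param a,b,c,d Nonnegative integer counts.
#' @return Object of class `table2x2`.
#' @export
contingency_2x2 <- function(a, b, c, d) {
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(is.na(counts)) || any(counts < 0) ||
      any(abs(counts - round(counts)) > 1e-9)) {
    stop_fm("cells must be nonnegative integers")
  }
  structure(as.list(round(counts)), class = "table2x2")
}

#' @export
print.table2x2 <- function(x, ...) {
  m <- matrix(c(x$a, x$b, x$c, x$d), 2, byrow = TRUE,
              dimnames = list(c("case", "control"),
                              c("exposed", "unexposed")))
  print(m)
  invisible(x)
}

#' Odds ratio with Woolf 95% confidence interval
#'
#' `OR = ad / bc`; the interval is `exp(log OR +/- 1.96 sqrt(1/a + 1/b +
#' 1/c + 1/d))`. A zero cell triggers the Haldane correction (0.5 added to
#' every cell) with a warning; a zero margin is an error. The Woolf
#' interval is one of several conventions in use for 2x2 tables; exact
#' conditional intervals can differ appreciably for small or unbalanced
#' tables.
#'
#' @param table A [contingency_2x2()].
#' @return List with `or` and `ci95` (length-2 vector).
#' @examples
#' odds_ratio(contingency_2x2(75, 256, 17, 228))
#' @export
odds_ratio <- function(table) {
  stopifnot(inherits(table, "table2x2"))
  a <- table$a; b <- table$b; c <- table$c; d <- table$d
  if (a + b == 0 || c + d == 0 || a + c == 0 || b + d == 0) {
    stop_fm("odds ratio undefined: zero margin")
  }
  if (min(a, b, c, d) == 0) {
    warning("zero cell; applying Haldane 0.5 correction", call. = FALSE)
    a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5
  }
  lor <- log(a) + log(d) - log(b) - log(c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  list(or = exp(lor),
       ci95 = exp(lor + c(-1, 1) * stats::qnorm(0.975) * se))
}

#' Fisher's exact test for a 2x2 table
#'
#' Conditional on both margins, the exposed-case count follows a
#' hypergeometric distribution. The two-sided p-value uses the
#' probability-mass rule: the sum of the probabilities of all tables with
#' the observed margins whose probability does not exceed that of the
#' observed table (ties resolved with a 1e-12 relative slack, so
#' analytically equal probabilities that differ only in floating point are
#' counted). Two-sided definitions for this test vary between tools; the
#' probability-mass rule is the common convention and the one implemented
#' here. One-sided alternatives are available.
#'
#' @param table A [contingency_2x2()].
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`
#'   (with respect to the exposed-case count `a`).
#' @return The p-value.
#' @examples
#' fisher_exact(contingency_2x2(75, 256, 17, 228))
#' @export
fisher_exact <- function(table, alternative = c("two.sided", "less",
                                                "greater")) {
  stopifnot(inherits(table, "table2x2"))
  alternative <- match.arg(alternative)
  a <- table$a; b <- table$b; c <- table$c; d <- table$d
  n <- a + b + c + d
  k <- a + c      # exposed margin
  m <- a + b      # case margin
  lo <- max(0L, k + m - n)
  hi <- min(k, m)
  support <- lo:hi
  probs <- stats::dhyper(support, k, n - k, m)
  p_obs <- probs[match(a, support)]
  p <- switch(alternative,
    two.sided = sum(probs[probs <= p_obs * (1 + 1e-12)]),
    less = sum(probs[support <= a]),
    greater = sum(probs[support >= a])
  )
  min(1, p)
}

#' Joint KIR3DS1 / HLA-B Bw4-80I carrier status
#'
#' Partitions each subject by the dominant-model compound genotype:
#' `both` (KIR3DS1 present and at least one HLA-B allele carrying the
#' Bw4-80I epitope), `kir_only`, `bw4_only`, `neither`, or `incomplete`
#' when the KIR flag is missing, either HLA-B call is missing, or an
#' HLA-B allele cannot be classified from the alignment. The compound
#' genotype links an activating NK-cell receptor with its putative
#' ligand, so both pieces of information are required for a call.
#'
#' @param cohort A [cohort_table()] with a `kir3ds1` column and HLA-B
#'   calls.
#' @param alignment A `protein_alignment` covering locus B.
#' @return Character vector (one status per subject), named by subject id.
#' @export
compound_status <- function(cohort, alignment) {
  sub <- cohort$subjects
  if (!"kir3ds1" %in% names(sub)) {
    stop_fm("cohort has no kir3ds1 column")
  }
  b1 <- sub$B_1; b2 <- sub$B_2
  cls1 <- classify_bw(b1, alignment)
  cls2 <- classify_bw(b2, alignment)
  incomplete <- is.na(sub$kir3ds1) | is.na(b1) | is.na(b2) |
    cls1 == "unknown" | cls2 == "unknown"
  bw4 <- cls1 == "Bw4_80I" | cls2 == "Bw4_80I"
  kir <- sub$kir3ds1
  out <- ifelse(incomplete, "incomplete",
         ifelse(kir & bw4, "both",
         ifelse(kir & !bw4, "kir_only",
         ifelse(!kir & bw4, "bw4_only", "neither"))))
  names(out) <- sub$id
  out
}

#' Carrier 2x2 table from a subject-level predicate
#'
#' Applies a dominant-model predicate to every subject and cross-tabulates
#' carrier status against phenotype. Subjects where the predicate is `NA`
#' (incomplete data) are excluded per-analysis, with the excluded count
#' logged and recorded — this is why carrier denominators can differ
#' between analyses of the same cohort.
#'
#' @param cohort A [cohort_table()].
#' @param predicate Function of a one-row subject data.frame returning
#'   `TRUE`, `FALSE` or `NA`.
#' @return A [contingency_2x2()] with attribute `"n_excluded"`.
#' @export
carrier_table <- function(cohort, predicate) {
  sub <- cohort$subjects
  status <- vapply(seq_len(nrow(sub)),
                   function(i) predicate(sub[i, , drop = FALSE]),
                   logical(1))
  keep <- !is.na(status)
  n_excl <- sum(!keep)
  if (n_excl) {
    fm_log(n_excl, " subject(s) with incomplete data excluded from ",
           "carrier table")
  }
  ph <- sub$phenotype[keep]
  st <- status[keep]
  if (!any(ph == "case") || !any(ph == "control")) {
    stop_fm("carrier table needs evaluable subjects in both groups")
  }
  tab <- contingency_2x2(
    a = sum(ph == "case" & st),
    b = sum(ph == "case" & !st),
    c = sum(ph == "control" & st),
    d = sum(ph == "control" & !st)
  )
  attr(tab, "n_excluded") <- n_excl
  tab
}

#' Table-6-style carrier predicates
#'
#' Ready-made subject predicates for the KIR3DS1 / Bw4-80I carrier
#' analyses:
#' * `predicate_kir3ds1()` — KIR3DS1 presence (`NA` when untyped).
#' * `predicate_bw4_80i(alignment)` — carries at least one HLA-B allele
#'   with the Bw4-80I epitope, judged over the *observed* alleles; `NA`
#'   only when no HLA-B call is observed. (Single-marker convention:
#'   carriage is counted over typed chromosomes.)
#' * `predicate_compound(alignment, status)` — compound-genotype category
#'   from [compound_status()] (`"both"`, `"kir_only"`, `"bw4_only"`);
#'   `NA` for incomplete subjects, so these analyses require complete
#'   KIR *and* HLA-B data.
#'
#' @param alignment A `protein_alignment` covering locus B.
#' @param status Which compound category counts as exposed.
#' @return A predicate function for [carrier_table()].
#' @name table6_predicates
NULL

#' @rdname table6_predicates
#' @export
predicate_kir3ds1 <- function() {
  function(s) s$kir3ds1
}

#' @rdname table6_predicates
#' @export
predicate_bw4_80i <- function(alignment) {
  function(s) {
    calls <- c(s$B_1, s$B_2)
    calls <- calls[!is.na(calls)]
    if (!length(calls)) return(NA)
    cls <- classify_bw(calls, alignment)
    if (any(cls == "Bw4_80I")) return(TRUE)
    if (all(cls == "unknown")) return(NA)
    FALSE
  }
}

#' @rdname table6_predicates
#' @export
predicate_compound <- function(alignment,
                               status = c("both", "kir_only", "bw4_only")) {
  status <- match.arg(status)
  function(s) {
    if (is.na(s$kir3ds1) || is.na(s$B_1) || is.na(s$B_2)) return(NA)
    cls <- classify_bw(c(s$B_1, s$B_2), alignment)
    if (any(cls == "unknown")) return(NA)
    bw4 <- any(cls == "Bw4_80I")
    cs <- if (s$kir3ds1 && bw4) "both"
          else if (s$kir3ds1) "kir_only"
          else if (bw4) "bw4_only"
          else "neither"
    cs == status
  }
}

#' Carrier association table in Table-6 layout
#'
#' Runs the five standard KIR3DS1 / Bw4-80I carrier analyses on a cohort
#' (KIR3DS1 without Bw4-80I, Bw4-80I without KIR3DS1, the compound
#' genotype, and the two single markers) and reports carrier fractions,
#' the two-sided exact p-value and the odds ratio with CI for each.
#'
#' @param cohort A [cohort_table()] with `kir3ds1` and HLA-B calls.
#' @param alignment A `protein_alignment` covering locus B.
#' @return A data.frame, one row per analysis.
#' @export
compound_genotype_table <- function(cohort, alignment) {
  specs <- list(
    "KIR3DS1_without_Bw4-80I" = predicate_compound(alignment, "kir_only"),
    "Bw4-80I_without_KIR3DS1" = predicate_compound(alignment, "bw4_only"),
    "KIR3DS1+Bw4-80I" = predicate_compound(alignment, "both"),
    "KIR3DS1" = predicate_kir3ds1(),
    "Bw4-80I" = predicate_bw4_80i(alignment)
  )
  rows <- lapply(names(specs), function(nm) {
    tab <- suppressMessages(carrier_table(cohort, specs[[nm]]))
    orci <- suppressWarnings(odds_ratio(tab))
    data.frame(
      genetic_variable = nm,
      carriers_cases = tab$a, n_cases = tab$a + tab$b,
      freq_cases_pct = round(100 * tab$a / (tab$a + tab$b), 1),
      carriers_controls = tab$c, n_controls = tab$c + tab$d,
      freq_controls_pct = round(100 * tab$c / (tab$c + tab$d), 1),
      p = fisher_exact(tab),
      or = orci$or, ci_lo = orci$ci95[1], ci_hi = orci$ci95[2],
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
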