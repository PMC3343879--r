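# EM estimation of multi-locus haplotype frequencies from unphased
# genotypes under Hardy-Weinberg equilibrium, with direct counting of
# phased data as the cross-check, case/control haplotype tests, and
# pairwise LD statistics.

HAP_SEP <- "|"

hap_id <- function(...) paste(..., sep = HAP_SEP)

# Enumerate the compatible haplotype pairs of one multi-locus genotype.
# geno: list of length-2 character vectors (one per locus, unordered).
# Returns list(h1 = character, h2 = character): each unordered compatible
# pair exactly once (phase fixed at the first heterozygous locus).
enumerate_diplotypes <- function(geno) {
  het <- vapply(geno, function(g) g[1] != g[2], logical(1))
  n_het <- sum(het)
  if (n_het == 0) {
    h <- hap_id(paste(vapply(geno, `[`, character(1), 1),
                      collapse = HAP_SEP))
    return(list(h1 = h, h2 = h))
  }
  free <- which(het)[-1L]  # first het locus anchors the phase
  n_free <- length(free)
  n_cfg <- 2L^n_free
  h1 <- character(n_cfg)
  h2 <- character(n_cfg)
  base1 <- vapply(geno, `[`, character(1), 1)
  base2 <- vapply(geno, `[`, character(1), 2)
  for (s in seq_len(n_cfg) - 1L) {
    a1 <- base1
    a2 <- base2
    if (n_free) {
      bits <- as.logical(bitwAnd(s, 2L^(seq_len(n_free) - 1L)))
      swap <- free[bits]
      a1[swap] <- base2[swap]
      a2[swap] <- base1[swap]
    }
    h1[s + 1L] <- paste(a1, collapse = HAP_SEP)
    h2[s + 1L] <- paste(a2, collapse = HAP_SEP)
  }
  list(h1 = h1, h2 = h2)
}

#' EM estimation of haplotype frequencies from unphased genotypes
#'
#' Standard genotype EM under Hardy-Weinberg equilibrium: the E-step
#' distributes each ambiguous multi-locus genotype over its compatible
#' haplotype pairs in proportion to the current frequency products, the
#' M-step re-estimates frequencies from the expected haplotype counts.
#' The log-likelihood is non-decreasing across iterations (asserted).
#' Several restarts from Dirichlet-perturbed uniform initial frequencies
#' guard against local maxima; the best final log-likelihood is kept and
#' the procedure is deterministic given `seed`.
#'
#' Subjects with any missing call at the requested loci are excluded (the
#' count is logged). Haplotypes with estimated frequency below 1e-6 are
#' pruned from the output.
#'
#' @param cohort A [cohort_table()].
#' @param loci Ordered locus vector (>= 1).
#' @param group Estimate within `"all"`, `"cases"` or `"controls"`.
#'   Estimating separately per group avoids biasing the within-group HWE
#'   assumption under case-control ascertainment.
#' @param tol Convergence tolerance: maximum absolute frequency change
#'   (default 1e-8).
#' @param max_iter Maximum EM iterations per restart (default 10000).
#' @param n_restarts Number of perturbed restarts (default 5).
#' @param seed RNG seed for the restarts (default 17).
#' @return Object of class `hla_em`: `loci`, `freq` (named, sorted
#'   descending, sums to 1), `loglik`, `loglik_trace`, `n_iter`,
#'   `converged`, `n_chromosomes`, `n_excluded`.
#' @export
em_haplotypes <- function(cohort, loci, group = c("all", "cases", "controls"),
                          tol = 1e-8, max_iter = 10000L, n_restarts = 5L,
                          seed = 17L) {
  group <- match.arg(group)
  if (!length(loci)) stop_fm("at least one locus is required")
  bad <- setdiff(loci, cohort$loci)
  if (length(bad)) stop_fm("locus not in cohort: ", paste(bad, collapse = ", "))
  sub <- cohort$subjects
  sub <- switch(group,
                all = sub,
                cases = sub[sub$phenotype == "case", , drop = FALSE],
                controls = sub[sub$phenotype == "control", , drop = FALSE])
  calls <- lapply(loci, function(loc) {
    cbind(sub[[paste0(loc, "_1")]], sub[[paste0(loc, "_2")]])
  })
  complete <- Reduce(`&`, lapply(calls, function(m) !is.na(m[, 1]) & !is.na(m[, 2])))
  n_excluded <- sum(!complete)
  if (n_excluded) {
    fm_log(n_excluded, " subject(s) with missing calls excluded from EM")
  }
  if (!any(complete)) stop_fm("no subject has complete calls at the loci")
  calls <- lapply(calls, function(m) m[complete, , drop = FALSE])
  n_sub <- sum(complete)

  # group identical genotypes into classes
  keys <- vapply(seq_len(n_sub), function(i) {
    paste(vapply(calls, function(m) paste(sort(m[i, ]), collapse = "/"),
                 character(1)), collapse = ";")
  }, character(1))
  tab <- table(keys)
  class_keys <- names(tab)
  n_class <- as.numeric(tab)
  rep_idx <- match(class_keys, keys)

  pair_h1 <- list(); pair_h2 <- list(); pair_cls <- list()
  for (g in seq_along(class_keys)) {
    i <- rep_idx[g]
    geno <- lapply(calls, function(m) m[i, ])
    dip <- enumerate_diplotypes(geno)
    pair_h1[[g]] <- dip$h1
    pair_h2[[g]] <- dip$h2
    pair_cls[[g]] <- rep(g, length(dip$h1))
  }
  h1 <- unlist(pair_h1); h2 <- unlist(pair_h2); cls <- unlist(pair_cls)
  haps <- sort(unique(c(h1, h2)))
  i1 <- match(h1, haps); i2 <- match(h2, haps)
  mult <- ifelse(i1 == i2, 1, 2)
  H <- length(haps)
  n_chrom <- 2 * n_sub

  run_em <- function(f) {
    trace <- numeric(0)
    ll_prev <- -Inf
    converged <- FALSE
    iter <- 0L
    repeat {
      iter <- iter + 1L
      w <- mult * f[i1] * f[i2]
      Pg <- as.vector(rowsum(w, cls, reorder = TRUE))
      ll <- sum(n_class * log(Pg))
      if (ll < ll_prev - 1e-9 * max(1, abs(ll_prev))) {
        stop_fm("EM log-likelihood decreased; this should not happen")
      }
      trace <- c(trace, ll)
      post <- w / Pg[cls]
      contrib <- n_class[cls] * post
      cnt <- numeric(H)
      agg <- rowsum(c(contrib, contrib), group = c(i1, i2), reorder = TRUE)
      cnt[as.integer(rownames(agg))] <- agg[, 1]
      f_new <- cnt / n_chrom
      delta <- max(abs(f_new - f))
      f <- f_new
      ll_prev <- ll
      if (delta < tol) { converged <- TRUE; break }
      if (iter >= max_iter) break
    }
    list(f = f, loglik = ll_prev, trace = trace, n_iter = iter,
         converged = converged)
  }

  best <- with_seed(seed, {
    best <- NULL
    for (r in seq_len(max(1L, n_restarts))) {
      f0 <- if (r == 1L) {
        rep(1 / H, H)
      } else {
        g <- stats::rgamma(H, shape = 1)
        p <- 0.5 * rep(1 / H, H) + 0.5 * g / sum(g)
        p / sum(p)
      }
      fit <- run_em(f0)
      if (is.null(best) || fit$loglik > best$loglik) best <- fit
    }
    best
  })
  if (!best$converged) {
    warning("EM did not converge within ", max_iter, " iterations",
            call. = FALSE)
  }
  f <- best$f
  names(f) <- haps
  f <- f[f >= 1e-6]
  f <- f / sum(f)
  f <- sort(f, decreasing = TRUE)
  structure(list(
    loci = loci, freq = f, loglik = best$loglik,
    loglik_trace = best$trace, n_iter = best$n_iter,
    converged = best$converged, n_chromosomes = n_chrom,
    n_excluded = n_excluded, group = group
  ), class = "hla_em")
}

#' @export
print.hla_em <- function(x, n = 10L, ...) {
  cat("<hla_em> loci ", paste(x$loci, collapse = "-"), ": ",
      length(x$freq), " haplotypes over ", x$n_chromosomes,
      " chromosomes; loglik = ", format(x$loglik), "; ",
      x$n_iter, " iterations",
      if (!x$converged) " (NOT converged)", "\n", sep = "")
  print(utils::head(x$freq, n))
  invisible(x)
}

#' Haplotype frequencies by direct counting of phased data
#'
#' Exact counting over known phase, used as the cross-check for the EM
#' estimates (on data without phase ambiguity the two agree exactly).
#'
#' @param phase A data.frame of phased haplotypes with columns
#'   `"<locus>.h1"` and `"<locus>.h2"` per locus (as produced in the
#'   `truth$phase` record of [generate_cohort()]).
#' @param loci Ordered locus vector.
#' @return Named numeric vector of haplotype frequencies (sums to 1).
#' @export
count_phased <- function(phase, loci) {
  if (!length(loci)) stop_fm("at least one locus is required")
  need <- c(paste0(loci, ".h1"), paste0(loci, ".h2"))
  miss <- setdiff(need, names(phase))
  if (length(miss)) {
    stop_fm("phase annotation missing column(s): ",
            paste(miss, collapse = ", "))
  }
  hap1 <- do.call(paste, c(phase[paste0(loci, ".h1")], sep = HAP_SEP))
  hap2 <- do.call(paste, c(phase[paste0(loci, ".h2")], sep = HAP_SEP))
  all_h <- c(hap1, hap2)
  if (anyNA(all_h) || any(grepl("NA", all_h, fixed = TRUE))) {
    stop_fm("phase annotation contains missing haplotypes")
  }
  tab <- table(all_h)
  f <- as.numeric(tab) / length(all_h)
  names(f) <- names(tab)
  sort(f, decreasing = TRUE)
}

#' Case-control test of one haplotype's frequency
#'
#' Converts the estimated haplotype frequencies of each group into counts
#' (frequency times the number of chromosomes, rounded half-up), forms the
#' 2x2 table of this haplotype versus all others, and tests the group
#' difference: chi-squared by default, switching to the exact test
#' whenever any expected cell count is below 5. The odds ratio comes from
#' the same table.
#'
#' @param est_cases,est_controls `hla_em` estimates over the same loci in
#'   the same order.
#' @param haplotype Haplotype identifier: either the `"a|b|..."` string or
#'   a character vector of per-locus alleles.
#' @return List with `p`, `or`, `ci95`, `method` (`"chisq"` or
#'   `"fisher"`), `table` (a `table2x2`), `freq_cases`, `freq_controls`.
#' @export
haplotype_case_control_test <- function(est_cases, est_controls, haplotype) {
  if (!identical(est_cases$loci, est_controls$loci)) {
    stop_fm("the two estimates cover different loci")
  }
  if (length(haplotype) > 1) haplotype <- paste(haplotype, collapse = HAP_SEP)
  fa <- unname(est_cases$freq[haplotype]); fa <- ifelse(is.na(fa), 0, fa)
  fb <- unname(est_controls$freq[haplotype]); fb <- ifelse(is.na(fb), 0, fb)
  if (fa == 0 && fb == 0) {
    stop_fm("haplotype '", haplotype, "' absent from both groups")
  }
  na <- est_cases$n_chromosomes
  nb <- est_controls$n_chromosomes
  a <- floor(fa * na + 0.5); b <- na - a
  c <- floor(fb * nb + 0.5); d <- nb - c
  tab <- contingency_2x2(a, b, c, d)
  # expected counts under the margins decide chi-squared vs exact
  m <- matrix(c(a, b, c, d), 2, byrow = TRUE)
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  method <- if (any(expected < 5)) "fisher" else "chisq"
  p <- if (method == "fisher") {
    fisher_exact(tab)
  } else {
    unname(stats::chisq.test(m, correct = FALSE)$p.value)
  }
  orci <- suppressWarnings(odds_ratio(tab))
  list(p = p, or = orci$or, ci95 = orci$ci95, method = method, table = tab,
       freq_cases = fa, freq_controls = fb)
}

#' Pairwise linkage-disequilibrium statistics
#'
#' For a biallelic x biallelic haplotype frequency table summing to one:
#' `D = p_AB - p_A p_B`, `D' = D / Dmax` with the standard bound
#' (`Dmax = min(p_A p_b, p_a p_B)` for positive D, `min(p_A p_B, p_a p_b)`
#' for negative D), and `r2 = D^2 / (p_A p_a p_B p_b)`. `|D'| = 1`
#' whenever one haplotype class has frequency zero.
#'
#' @param freqs 2x2 numeric matrix of haplotype frequencies (rows = alleles
#'   at the first locus, columns = alleles at the second), summing to 1.
#' @return Object of class `ld_stats`: `d`, `d_prime` (signed),
#'   `abs_d_prime`, `r2`, plus the marginal allele frequencies.
#' @export
ld_pair <- function(freqs) {
  freqs <- as.matrix(freqs)
  if (!all(dim(freqs) == c(2, 2))) stop_fm("freqs must be a 2x2 matrix")
  if (any(freqs < -1e-12)) stop_fm("frequencies must be nonnegative")
  if (abs(sum(freqs) - 1) > 1e-8) stop_fm("frequencies must sum to 1")
  pA <- sum(freqs[1, ]); pa <- 1 - pA
  pB <- sum(freqs[, 1]); pb <- 1 - pB
  if (min(pA, pa, pB, pb) <= 0) {
    stop_fm("LD is undefined for a monomorphic locus")
  }
  D <- freqs[1, 1] - pA * pB
  dmax <- if (D >= 0) min(pA * pb, pa * pB) else min(pA * pB, pa * pb)
  d_prime <- if (D == 0) 0 else D / dmax
  r2 <- D^2 / (pA * pa * pB * pb)
  structure(list(
    d = D, d_prime = d_prime, abs_d_prime = abs(d_prime), r2 = r2,
    p_first = pA, p_second = pB,
    alleles = list(first = rownames(freqs), second = colnames(freqs))
  ), class = "ld_stats")
}

#' @export
print.ld_stats <- function(x, ...) {
  cat(sprintf("LD: D = %.4g, |D'| = %.4g, r2 = %.4g\n",
              x$d, x$abs_d_prime, x$r2))
  invisible(x)
}

#' Write a haplotype frequency comparison as TSV
#'
#' Per-locus allele columns plus case/control frequencies, p and OR for
#' each haplotype present in either group.
#'
#' @param est_cases,est_controls `hla_em` estimates over the same loci.
#' @param path Output path.
#' @param min_freq Only haplotypes reaching this frequency in either group
#'   are written (default 0.005).
#' @return The written data.frame, invisibly.
#' @export
write_haplotype_tsv <- function(est_cases, est_controls, path,
                                min_freq = 0.005) {
  haps <- union(names(est_cases$freq), names(est_controls$freq))
  fa <- ifelse(is.na(est_cases$freq[haps]), 0, est_cases$freq[haps])
  fb <- ifelse(is.na(est_controls$freq[haps]), 0, est_controls$freq[haps])
  keep <- pmax(fa, fb) >= min_freq
  haps <- haps[keep]; fa <- fa[keep]; fb <- fb[keep]
  parts <- do.call(rbind, strsplit(haps, HAP_SEP, fixed = TRUE))
  colnames(parts) <- est_cases$loci
  stats <- lapply(haps, function(h) {
    res <- tryCatch(haplotype_case_control_test(est_cases, est_controls, h),
                    error = function(e) list(p = NA_real_, or = NA_real_))
    data.frame(p = res$p, or = res$or)
  })
  df <- cbind(as.data.frame(parts, stringsAsFactors = FALSE),
              freq_cases = unname(fa), freq_controls = unname(fb),
              do.call(rbind, stats))
  df <- df[order(df$p), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(df)
}
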