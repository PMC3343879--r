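#' Construct a case-control HLA cohort table
#'
#' The central data container: one row per subject with phenotype, sex,
#' cohort label, ancestry principal-component scores, two classical HLA
#' allele calls per locus and an optional KIR3DS1 presence flag. Allele
#' strings are validated on construction; missing calls are preserved.
#'
#' @param subjects A data.frame with columns `id`, `phenotype`
#'   (`"case"`/`"control"`), `sex`, `cohort`, zero or more `pc1..pcK`
#'   columns, `"<locus>_1"`/`"<locus>_2"` columns per locus, and optionally
#'   `kir3ds1` (logical or 0/1).
#' @param loci Character vector of loci present; defaults to the loci whose
#'   call columns are found in `subjects`.
#' @param meta Optional list of provenance notes.
#' @return An object of class `cohort_table`.
#' @export
cohort_table <- function(subjects, loci = NULL, meta = list()) {
  stopifnot(is.data.frame(subjects))
  required <- c("id", "phenotype", "sex", "cohort")
  miss <- setdiff(required, names(subjects))
  if (length(miss)) {
    stop_fm("cohort is missing required column(s): ", paste(miss, collapse = ", "))
  }
  subjects$id <- as.character(subjects$id)
  if (anyDuplicated(subjects$id)) {
    dup <- subjects$id[duplicated(subjects$id)][1L]
    stop_fm("duplicate subject id: '", dup, "'")
  }
  subjects$phenotype <- as.character(subjects$phenotype)
  if (!all(subjects$phenotype %in% c("case", "control"))) {
    bad <- setdiff(unique(subjects$phenotype), c("case", "control"))
    stop_fm("phenotype must be 'case' or 'control'; found: ",
            paste(bad, collapse = ", "))
  }
  if (is.null(loci)) {
    loci <- HLA_LOCI[paste0(HLA_LOCI, "_1") %in% names(subjects)]
  }
  if (!length(loci)) stop_fm("no HLA call columns found")
  for (loc in loci) {
    for (k in 1:2) {
      col <- paste0(loc, "_", k)
      if (!col %in% names(subjects)) {
        stop_fm("missing allele column '", col, "'")
      }
      calls <- as.character(subjects[[col]])
      # validate row by row so errors can name the offender
      parsed <- tryCatch(parse_allele(calls, locus = loc), error = function(e) e)
      if (inherits(parsed, "error")) {
        ok <- grepl(.allele_regex, calls) | is.na(calls) | calls %in% c("", "NA")
        if (any(!ok)) {
          row <- which(!ok)[1L]
          stop_fm("row ", row, ": malformed allele '", calls[row],
                  "' in column ", col)
        }
        stop_fm("column ", col, ": ", conditionMessage(parsed))
      }
      subjects[[col]] <- parsed$name
    }
  }
  if ("kir3ds1" %in% names(subjects)) {
    subjects$kir3ds1 <- .parse_flag(subjects$kir3ds1)
  }
  pcs <- grep("^pc[0-9]+$", names(subjects), value = TRUE)
  structure(
    list(subjects = subjects, loci = loci, pc_cols = pcs, meta = meta),
    class = "cohort_table"
  )
}

.parse_flag <- function(x) {
  if (is.logical(x)) return(x)
  x <- as.character(x)
  out <- rep(NA, length(x))
  out[x %in% c("1", "TRUE", "true", "T", "yes")] <- TRUE
  out[x %in% c("0", "FALSE", "false", "F", "no")] <- FALSE
  out
}

#' @export
print.cohort_table <- function(x, ...) {
  cat("<cohort_table> ", nrow(x$subjects), " subjects (",
      n_cases(x), " cases / ", n_controls(x), " controls); loci: ",
      paste(x$loci, collapse = ", "), "; ", length(x$pc_cols), " PCs\n",
      sep = "")
  invisible(x)
}

#' @rdname cohort_table
#' @param x A `cohort_table`.
#' @export
n_cases <- function(x) sum(x$subjects$phenotype == "case")

#' @rdname cohort_table
#' @export
n_controls <- function(x) sum(x$subjects$phenotype == "control")

#' Read a cohort from a delimited text file
#'
#' One subject per row with a header. Allele strings are validated;
#' malformed values are reported with their row number and token. Missing
#' calls (empty, `NA`) are preserved, not dropped.
#'
#' @param path Path to a TSV/CSV file.
#' @param sep Field delimiter (default tab).
#' @param loci Loci to load; defaults to all call columns present.
#' @return A [cohort_table()].
#' @export
read_cohort <- function(path, sep = "\t", loci = NULL) {
  if (!file.exists(path)) stop_fm("cohort file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", check.names = FALSE,
                          na.strings = c("NA", ""), quote = "",
                          comment.char = "")
  pcs <- grep("^pc[0-9]+$", names(df), value = TRUE)
  for (p in pcs) df[[p]] <- as.numeric(df[[p]])
  cohort_table(df, loci = loci, meta = list(source = path))
}

#' Write a cohort to a delimited text file
#'
#' Inverse of [read_cohort()]: a read-write-read round trip is the identity
#' on valid files.
#'
#' @param cohort A `cohort_table`.
#' @param path Output path.
#' @param sep Field delimiter.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, sep = "\t") {
  utils::write.table(cohort$subjects, path, sep = sep, quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Per-locus allele frequencies
#'
#' Frequencies are computed over non-missing chromosomes (two per subject
#' per locus); the number of excluded (missing) chromosomes is logged.
#' Within each locus and group the frequencies sum to one over the observed
#' alleles.
#'
#' @param cohort A `cohort_table`.
#' @param group `"all"`, `"cases"` or `"controls"`.
#' @param loci Loci to tabulate (default: all in the cohort).
#' @return A data.frame with columns `locus`, `allele`, `count`, `freq`.
#' @export
allele_frequencies <- function(cohort,
                               group = c("all", "cases", "controls"),
                               loci = cohort$loci) {
  group <- match.arg(group)
  sub <- cohort$subjects
  sub <- switch(group,
                all = sub,
                cases = sub[sub$phenotype == "case", , drop = FALSE],
                controls = sub[sub$phenotype == "control", , drop = FALSE])
  if (!nrow(sub)) stop_fm("group '", group, "' is empty")
  out <- list()
  n_excluded <- 0L
  for (loc in loci) {
    calls <- c(sub[[paste0(loc, "_1")]], sub[[paste0(loc, "_2")]])
    n_excluded <- n_excluded + sum(is.na(calls))
    calls <- calls[!is.na(calls)]
    if (!length(calls)) next
    tab <- table(calls)
    out[[loc]] <- data.frame(
      locus = loc,
      allele = names(tab),
      count = as.integer(tab),
      freq = as.numeric(tab) / length(calls),
      stringsAsFactors = FALSE
    )
  }
  if (n_excluded > 0) {
    fm_log(n_excluded, " missing chromosome(s) excluded from ", group,
           " frequency denominators")
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Minor-allele-frequency filter on control-group frequencies
#'
#' Retains alleles whose frequency in the *control* group is strictly
#' greater than `threshold`; case frequencies never enter the decision, so
#' the retained set is invariant to any permutation of case genotypes. An
#' allele at exactly the threshold is excluded.
#'
#' @param freqs A frequency data.frame from
#'   `allele_frequencies(cohort, "controls")` (columns `allele`, `freq`).
#' @param threshold Frequency threshold in (0, 0.5); default 0.01.
#' @return Character vector of retained allele names.
#' @export
maf_filter <- function(freqs, threshold = 0.01) {
  stopifnot(is.data.frame(freqs), all(c("allele", "freq") %in% names(freqs)))
  if (!(threshold > 0 && threshold < 0.5)) {
    stop_fm("threshold must be in (0, 0.5)")
  }
  freqs$allele[freqs$freq > threshold]
}

#' @describeIn maf_filter Convenience wrapper computing control frequencies
#'   from a cohort before filtering.
#' @param cohort A `cohort_table`.
#' @param loci Loci to consider.
#' @export
maf_filter_cohort <- function(cohort, threshold = 0.01, loci = cohort$loci) {
  maf_filter(allele_frequencies(cohort, "controls", loci = loci), threshold)
}

#' Collapse a cohort to two-digit allele resolution
#'
#' Truncates every call at the first colon so that two-digit analyses run
#' over separately collapsed allele columns.
#'
#' @param cohort A `cohort_table`.
#' @return A new `cohort_table` with two-digit calls.
#' @export
collapse_two_digit <- function(cohort) {
  sub <- cohort$subjects
  for (loc in cohort$loci) {
    for (k in 1:2) {
      col <- paste0(loc, "_", k)
      sub[[col]] <- allele_two_digit(sub[[col]])
    }
  }
  cohort_table(sub, loci = cohort$loci,
               meta = c(cohort$meta, list(resolution = "two_digit")))
}

#' Additive allele dosage matrix
#'
#' One column per allele, dosage 0/1/2 = number of the subject's two calls
#' equal to that allele. A subject with any missing call at a locus gets
#' `NA` for every allele of that locus (dosages over a half-observed
#' genotype would undercount).
#'
#' @param cohort A `cohort_table`.
#' @param alleles Alleles to code (default: every allele observed).
#' @return Numeric matrix, subjects x alleles, with subject ids as rownames.
#' @export
allele_dosage_matrix <- function(cohort, alleles = NULL) {
  sub <- cohort$subjects
  if (is.null(alleles)) {
    alleles <- sort(unique(unlist(lapply(cohort$loci, function(loc) {
      stats::na.omit(c(sub[[paste0(loc, "_1")]], sub[[paste0(loc, "_2")]]))
    }))))
  }
  out <- matrix(NA_real_, nrow(sub), length(alleles),
                dimnames = list(sub$id, alleles))
  for (j in seq_along(alleles)) {
    al <- alleles[j]
    loc <- allele_locus(al)
    a1 <- sub[[paste0(loc, "_1")]]
    a2 <- sub[[paste0(loc, "_2")]]
    dose <- (a1 == al) + (a2 == al)
    dose[is.na(a1) | is.na(a2)] <- NA
    out[, j] <- dose
  }
  out
}

#' Covariate design matrix from a cohort
#'
#' Builds the adjustment set used throughout the analyses: a sex indicator,
#' cohort fixed-effect indicator columns (first level as reference), and
#' the ancestry principal-component scores.
#'
#' @param cohort A `cohort_table`.
#' @param n_pcs Number of PCs to include (default: all available).
#' @param include Which covariate blocks to include.
#' @return Numeric matrix (no intercept column), or `NULL` when empty.
#' @export
covariate_matrix <- function(cohort, n_pcs = NULL,
                             include = c("sex", "cohort", "pcs")) {
  sub <- cohort$subjects
  blocks <- list()
  if ("sex" %in% include && length(unique(sub$sex)) > 1) {
    lev <- sort(unique(as.character(sub$sex)))
    for (l in lev[-1]) {
      blocks[[paste0("sex", l)]] <- as.numeric(sub$sex == l)
    }
  }
  if ("cohort" %in% include && length(unique(sub$cohort)) > 1) {
    lev <- sort(unique(as.character(sub$cohort)))
    for (l in lev[-1]) {
      blocks[[paste0("cohort", l)]] <- as.numeric(sub$cohort == l)
    }
  }
  if ("pcs" %in% include && length(cohort$pc_cols)) {
    pcs <- cohort$pc_cols
    if (!is.null(n_pcs)) pcs <- utils::head(pcs, n_pcs)
    for (p in pcs) blocks[[p]] <- as.numeric(sub[[p]])
  }
  if (!length(blocks)) return(NULL)
  do.call(cbind, blocks)
}

#' Phenotype as a 0/1 vector
#'
#' @param cohort A `cohort_table`.
#' @return Numeric vector, 1 for cases and 0 for controls.
#' @export
phenotype_vector <- function(cohort) {
  as.numeric(cohort$subjects$phenotype == "case")
}

#' Carrier (dominant-model) frequency of a predicate
#'
#' Fraction of subjects in a group satisfying a subject-level predicate,
#' excluding subjects where the predicate is `NA` (incomplete data), e.g.
#' 75 carriers among 331 evaluable cases gives 22.7%.
#'
#' @param cohort A `cohort_table`.
#' @param predicate Function mapping a one-row subject data.frame to
#'   `TRUE`, `FALSE` or `NA`.
#' @param group `"cases"`, `"controls"` or `"all"`.
#' @return List with `carriers`, `n`, `freq`.
#' @export
carrier_frequency <- function(cohort, predicate,
                              group = c("cases", "controls", "all")) {
  group <- match.arg(group)
  sub <- cohort$subjects
  sub <- switch(group,
                all = sub,
                cases = sub[sub$phenotype == "case", , drop = FALSE],
                controls = sub[sub$phenotype == "control", , drop = FALSE])
  if (!nrow(sub)) stop_fm("group '", group, "' is empty")
  status <- vapply(seq_len(nrow(sub)),
                   function(i) predicate(sub[i, , drop = FALSE]),
                   logical(1))
  keep <- !is.na(status)
  list(carriers = sum(status[keep]), n = sum(keep),
       freq = sum(status[keep]) / sum(keep))
}
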