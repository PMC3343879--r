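#' Bonferroni entry thresholds for stepwise selection
#'
#' Stopping thresholds used for forward stepwise modelling, each the 0.05
#' Bonferroni bound for the corresponding candidate count: 0.0006 for 88
#' class I + class II candidate alleles, 0.00096 for 52 class I candidate
#' alleles, and 0.0001 for 480 amino-acid residue candidates.
#'
#' @export
STEPWISE_THRESHOLDS <- c(
  class1_class2_alleles = 0.0006,
  class1_alleles = 0.00096,
  residues = 0.0001
)

#' Forward stepwise selection of independently associated terms
#'
#' Starts from an empty model (or from `seed_term`) and iteratively adds
#' the candidate with the smallest conditional Wald p-value, each
#' candidate being tested conditional on all previously selected terms
#' (plus the fixed covariates). Selection stops when no remaining
#' candidate reaches `threshold`. There is no backward elimination. Ties
#' at entry are broken by larger `|beta|`, then lexicographic term name,
#' so selection order is deterministic given the data. After selection the
#' final model is refit jointly and per-term multivariate Wald statistics
#' are reported alongside the at-entry (stepwise-univariate) results.
#'
#' Aliased candidates (e.g. a duplicate of a selected term) have no
#' conditional estimate and can never enter.
#'
#' @param y Phenotype (0/1 or case/control).
#' @param X Candidate dosage matrix (already MAF-filtered), one column per
#'   candidate term.
#' @param covariates Optional covariate matrix, kept fixed throughout.
#' @param threshold Entry p-value threshold in (0, 1); see
#'   [STEPWISE_THRESHOLDS].
#' @param seed_term Optional candidate forced in as the first step (e.g.
#'   the locus-wide top allele).
#' @return An object of class `stepwise_trace`: `steps` (data.frame of
#'   selected terms with at-entry statistics, in entry order), `final`
#'   (data.frame of joint-refit multivariate statistics), `threshold`,
#'   `n_candidates`.
#' @export
stepwise_select <- function(y, X, covariates = NULL, threshold,
                            seed_term = NULL) {
  if (!(threshold >= 0 && threshold <= 1)) {
    stop_fm("threshold must be in [0, 1]")
  }
  X <- .as_named_matrix(X, "term")
  candidates <- colnames(X)
  if (!is.null(seed_term) && !seed_term %in% candidates) {
    stop_fm("seed_term '", seed_term, "' is not among the candidates")
  }
  selected <- character(0)
  steps <- list()

  test_candidates <- function(pool, selected) {
    cond <- if (length(selected)) X[, selected, drop = FALSE] else NULL
    res <- assoc_scan(y, X[, pool, drop = FALSE],
                      covariates = covariates, condition = cond)
    res[!is.na(res$p) & !res$unstable, , drop = FALSE]
  }

  if (!is.null(seed_term)) {
    res <- suppressWarnings(
      fit_logistic(y, X[, seed_term], covariates = covariates,
                   term = seed_term)
    )
    selected <- seed_term
    steps[[seed_term]] <- cbind(as.data.frame(res), forced = TRUE)
  }

  repeat {
    pool <- setdiff(candidates, selected)
    if (!length(pool)) break
    res <- test_candidates(pool, selected)
    if (!nrow(res)) break
    best <- res[1L, , drop = FALSE]  # assoc_scan already applies tie-breaks
    if (!(best$p < threshold)) break
    selected <- c(selected, best$term)
    best$error <- NULL
    steps[[best$term]] <- cbind(best, forced = FALSE)
  }

  final <- NULL
  if (length(selected)) {
    rows <- lapply(selected, function(term) {
      others <- setdiff(selected, term)
      cond <- if (length(others)) X[, others, drop = FALSE] else NULL
      as.data.frame(suppressWarnings(
        fit_logistic(y, X[, term], covariates = covariates,
                     condition = cond, term = term)
      ))
    })
    final <- do.call(rbind, rows)
    rownames(final) <- NULL
  }
  steps_df <- if (length(steps)) {
    out <- do.call(rbind, steps)
    rownames(out) <- NULL
    out
  } else NULL
  structure(list(
    steps = steps_df,
    final = final,
    threshold = threshold,
    n_candidates = length(candidates),
    seed_term = seed_term
  ), class = "stepwise_trace")
}

#' @export
print.stepwise_trace <- function(x, ...) {
  n_sel <- if (is.null(x$steps)) 0L else nrow(x$steps)
  cat("<stepwise_trace> ", n_sel, " of ", x$n_candidates,
      " candidate(s) selected at entry threshold p < ", x$threshold, "\n",
      sep = "")
  if (n_sel) {
    print(x$steps[, c("term", "p", "or")], ...)
  }
  invisible(x)
}

#' @describeIn stepwise_select Number of selected terms.
#' @param trace A `stepwise_trace`.
#' @export
n_selected <- function(trace) {
  if (is.null(trace$steps)) 0L else nrow(trace$steps)
}

#' Residual-signal (conditional) association test
#'
#' Single conditional fit of a focal term given a set of conditioning
#' terms, supporting residual-effect workflows such as testing whether a
#' class II allele retains signal after conditioning on a class I allele,
#' or whether an allele's signal survives conditioning on all of its own
#' coding residues.
#'
#' @param y Phenotype.
#' @param X Dosage matrix containing the focal and conditioning columns.
#' @param focal Column name of the focal term.
#' @param conditioning Column names to condition on (must not include
#'   `focal`).
#' @param covariates Optional covariate matrix.
#' @return An `hla_assoc` result.
#' @export
residual_signal_test <- function(y, X, focal, conditioning,
                                 covariates = NULL) {
  X <- .as_named_matrix(X, "term")
  if (focal %in% conditioning) {
    stop_fm("focal term must not be in the conditioning set")
  }
  missing_cols <- setdiff(c(focal, conditioning), colnames(X))
  if (length(missing_cols)) {
    stop_fm("column(s) absent from X: ", paste(missing_cols, collapse = ", "))
  }
  cond <- if (length(conditioning)) X[, conditioning, drop = FALSE] else NULL
  fit_logistic(y, X[, focal], covariates = covariates, condition = cond,
               term = focal)
}

#' Write a stepwise trace as TSV
#'
#' One row per selected term with the at-entry (stepwise-univariate) and
#' joint-refit (multivariate) p-values and odds ratios side by side.
#'
#' @param trace A `stepwise_trace`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_stepwise_tsv <- function(trace, path) {
  if (is.null(trace$steps)) {
    df <- data.frame(term = character(0))
  } else {
    df <- data.frame(
      term = trace$steps$term,
      stepwise_p = trace$steps$p,
      stepwise_or = trace$steps$or,
      multivariate_p = trace$final$p[match(trace$steps$term, trace$final$term)],
      multivariate_or = trace$final$or[match(trace$steps$term, trace$final$term)],
      stringsAsFactors = FALSE
    )
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}
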