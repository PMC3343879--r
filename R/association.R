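#' Omnibus likelihood-ratio test for a multi-residue position
#'
#' Joint test of all residue levels at one protein position: the model
#' containing k-1 residue dosage columns (one reference residue dropped)
#' is compared with the covariates-only null by a likelihood-ratio test
#' on k-1 degrees of freedom. The statistic is invariant to the choice of
#' reference residue; by default the most frequent residue is dropped.
#'
#' @param y Phenotype (0/1 or case/control).
#' @param position_dosages Numeric matrix with one column per residue at
#'   the position (each column an additive 0/1/2 dosage). At least two
#'   columns; with a single residue use [fit_logistic()].
#' @param covariates Optional covariate matrix.
#' @param reference Residue column to drop: `"most_common"` (default) or a
#'   column name.
#' @return List with `p`, `stat` (chi-squared LRT statistic), `df`,
#'   `reference`, `n`.
#' @export
omnibus_position_test <- function(y, position_dosages, covariates = NULL,
                                  reference = "most_common") {
  y <- .as_binary_phenotype(y)
  D <- .as_named_matrix(position_dosages, "res")
  if (ncol(D) < 2) {
    stop_fm("omnibus test needs >= 2 residue columns; ",
            "use fit_logistic() for a single residue")
  }
  covariates <- .as_named_matrix(covariates, "cov")
  keep <- !is.na(y) & stats::complete.cases(D)
  if (!is.null(covariates)) keep <- keep & stats::complete.cases(covariates)
  y <- y[keep]
  D <- D[keep, , drop = FALSE]
  covariates <- if (!is.null(covariates)) covariates[keep, , drop = FALSE]
  ref <- if (identical(reference, "most_common")) {
    colnames(D)[which.max(colMeans(D))]
  } else {
    if (!reference %in% colnames(D)) stop_fm("unknown reference column")
    reference
  }
  Dred <- D[, setdiff(colnames(D), ref), drop = FALSE]
  null_fit <- logit_core(y, covariates)
  full_fit <- logit_core(y, cbind(covariates, Dred))
  stat <- null_fit$deviance - full_fit$deviance
  df <- full_fit$rank - null_fit$rank
  if (df < 1) stop_fm("residue columns are fully aliased with the null model")
  list(p = stats::pchisq(stat, df, lower.tail = FALSE),
       stat = stat, df = df, reference = ref, n = length(y))
}

#' Association scan over a set of dosage columns
#'
#' Runs [fit_logistic()] for every column and returns one row per term,
#' ranked by ascending p-value with deterministic tie-breaks (descending
#' `|beta|`, then lexicographic term name). Terms whose fit fails are
#' reported with `NA` statistics and an error message; the scan continues.
#'
#' @param y Phenotype (0/1 or case/control).
#' @param X Numeric matrix of dosage columns (alleles, residues, markers).
#' @param covariates Optional covariate matrix.
#' @param condition Optional conditioning dosage matrix/vector applied to
#'   every term.
#' @return A data.frame of association results (one row per column), with
#'   failed terms last; failure messages in the `error` column.
#' @export
assoc_scan <- function(y, X, covariates = NULL, condition = NULL) {
  X <- .as_named_matrix(X, "term")
  if (ncol(X) == 0) {
    return(data.frame(term = character(0), beta = numeric(0), se = numeric(0),
                      or = numeric(0), ci_lo = numeric(0), ci_hi = numeric(0),
                      p = numeric(0), n_cases = integer(0),
                      n_controls = integer(0), conditioned_on = character(0),
                      unstable = logical(0), error = character(0),
                      stringsAsFactors = FALSE))
  }
  rows <- lapply(colnames(X), function(term) {
    res <- tryCatch(
      suppressWarnings(
        fit_logistic(y, X[, term], covariates = covariates,
                     condition = condition, term = term)
      ),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      data.frame(term = term, beta = NA_real_, se = NA_real_, or = NA_real_,
                 ci_lo = NA_real_, ci_hi = NA_real_, p = NA_real_,
                 n_cases = NA_integer_, n_controls = NA_integer_,
                 conditioned_on = "", unstable = NA,
                 error = conditionMessage(res), stringsAsFactors = FALSE)
    } else {
      cbind(as.data.frame(res), error = "", stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  ord <- order(out$p, -abs(out$beta), out$term, na.last = TRUE)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cross-cohort heterogeneity of an effect estimate
#'
#' Fixed-effect inverse-variance pooling of per-cohort log-odds estimates
#' with Cochran's Q and the heterogeneity index
#' `I2 = max(0, (Q - df) / Q) * 100`, the percentage of variation in the
#' estimates attributable to between-cohort heterogeneity (roughly: 25
#' low, 50 moderate, 75 high).
#'
#' @param beta Numeric vector of per-cohort log-odds ratios (>= 2).
#' @param se Matching standard errors (finite, positive).
#' @param term Optional label.
#' @return An object of class `het_result`: `term`, `q`, `df`, `p_q`,
#'   `i2` (percent), `pooled_beta`, `pooled_se`, and the per-cohort
#'   inputs.
#' @export
heterogeneity <- function(beta, se, term = NA_character_) {
  beta <- as.numeric(beta)
  se <- as.numeric(se)
  if (length(beta) != length(se)) stop_fm("beta and se differ in length")
  if (length(beta) < 2) {
    stop_fm("heterogeneity needs >= 2 cohorts (df would be 0)")
  }
  if (!all(is.finite(beta)) || !all(is.finite(se)) || any(se <= 0)) {
    stop_fm("all beta and se must be finite with se > 0")
  }
  w <- 1 / se^2
  pooled <- sum(w * beta) / sum(w)
  q <- sum(w * (beta - pooled)^2)
  df <- length(beta) - 1L
  i2 <- if (q > 0) max(0, (q - df) / q) * 100 else 0
  structure(list(
    term = term, q = q, df = df,
    p_q = stats::pchisq(q, df, lower.tail = FALSE),
    i2 = i2,
    pooled_beta = pooled, pooled_se = sqrt(1 / sum(w)),
    beta = beta, se = se
  ), class = "het_result")
}

#' @export
print.het_result <- function(x, ...) {
  cat(sprintf("Heterogeneity%s: Q = %.3g on %d df (p = %.3g), I2 = %.1f%%\n",
              if (!is.na(x$term)) paste0(" [", x$term, "]") else "",
              x$q, x$df, x$p_q, x$i2))
  invisible(x)
}

#' Write an association result table as TSV
#'
#' Plain tab-separated output (term, case/control frequencies when
#' supplied, p, OR, CI, conditioning set) for diffable result files.
#'
#' @param results Data.frame as returned by [assoc_scan()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_assoc_tsv <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
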