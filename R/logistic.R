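# Logistic fitting core. Models are fit by iteratively reweighted least
# squares (stats::glm.fit) to a relative log-likelihood change of 1e-10
# with at most 100 iterations. Rank-deficient designs are handled by
# pivoting: aliased columns get NA coefficients and are reported.

logit_core <- function(y, X, epsilon = 1e-10, maxit = 100L) {
  design <- cbind(`(Intercept)` = rep(1, length(y)), X)
  fit <- suppressWarnings(stats::glm.fit(
    design, y,
    family = stats::binomial(),
    control = stats::glm.control(epsilon = epsilon, maxit = as.integer(maxit))
  ))
  coefs <- fit$coefficients
  aliased <- names(coefs)[is.na(coefs)]
  se <- rep(NA_real_, length(coefs))
  names(se) <- names(coefs)
  p1 <- seq_len(fit$rank)
  Qr <- fit$qr
  covmat <- chol2inv(Qr$qr[p1, p1, drop = FALSE])
  est_names <- names(coefs)[Qr$pivot[p1]]
  se[est_names] <- sqrt(diag(covmat))
  list(coef = coefs, se = se, aliased = aliased,
       deviance = fit$deviance, rank = fit$rank,
       converged = fit$converged, n = length(y))
}

.as_binary_phenotype <- function(y) {
  if (is.factor(y)) y <- as.character(y)
  if (is.character(y)) {
    if (!all(y %in% c("case", "control"))) {
      stop_fm("character phenotype must be 'case'/'control'")
    }
    y <- as.numeric(y == "case")
  }
  if (!all(y %in% c(0, 1))) stop_fm("phenotype must be binary")
  y
}

.as_named_matrix <- function(x, prefix) {
  if (is.null(x)) return(NULL)
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x)) {
    x <- matrix(x, ncol = 1)
  }
  if (is.null(colnames(x)) && ncol(x) > 0) {
    colnames(x) <- paste0(prefix, seq_len(ncol(x)))
  }
  storage.mode(x) <- "double"
  x
}

#' Covariate-adjusted additive logistic association test
#'
#' Fits `phenotype ~ x + covariates + condition` by logistic regression
#' with additive (0/1/2) coding of the focal dosage and reports the Wald
#' test on the focal term. Conditioning is implemented by entering each
#' conditioned term as an additional covariate. Rows with missing values
#' in any term are dropped (complete-case). Aliased covariate or
#' conditioning columns are dropped with a warning; an aliased *focal*
#' term yields an `NA` effect with a warning, never a spurious p-value.
#' Fits with `|beta| > 15` or that fail to converge are flagged
#' `unstable` (a symptom of perfect separation).
#'
#' @param y Phenotype: 0/1 numeric, or `"case"`/`"control"`.
#' @param x Focal dosage vector (additive coding).
#' @param covariates Optional numeric matrix/data.frame of covariates.
#' @param condition Optional matrix/vector of dosage terms to condition on.
#' @param term Label for the focal term.
#' @return An object of class `hla_assoc` with fields `term`, `beta`,
#'   `se`, `or_`, `ci95`, `p`, `n_cases`, `n_controls`, `conditioned_on`,
#'   `covariates`, `converged`, `unstable`.
#' @examples
#' y <- rep(c(1, 0), c(100, 100))
#' x <- rbinom(200, 2, 0.3)
#' fit_logistic(y, x, term = "toy")
#' @export
fit_logistic <- function(y, x, covariates = NULL, condition = NULL,
                         term = "term") {
  y <- .as_binary_phenotype(y)
  x <- as.numeric(x)
  covariates <- .as_named_matrix(covariates, "cov")
  condition <- .as_named_matrix(condition, "cond")
  keep <- !is.na(y) & !is.na(x)
  if (!is.null(covariates)) keep <- keep & stats::complete.cases(covariates)
  if (!is.null(condition)) keep <- keep & stats::complete.cases(condition)
  y <- y[keep]; x <- x[keep]
  covariates <- if (!is.null(covariates)) covariates[keep, , drop = FALSE]
  condition <- if (!is.null(condition)) condition[keep, , drop = FALSE]
  if (!any(y == 1) || !any(y == 0)) {
    stop_fm("phenotype must contain both cases and controls")
  }
  if (stats::var(x) == 0) {
    stop_fm("focal term '", term, "' has zero variance")
  }
  X <- cbind(covariates, condition)
  X <- cbind(X, structure(x, class = NULL))
  colnames(X)[ncol(X)] <- ".focal"
  fit <- logit_core(y, X)
  if (length(setdiff(fit$aliased, ".focal"))) {
    warning("dropped aliased column(s): ",
            paste(setdiff(fit$aliased, ".focal"), collapse = ", "),
            call. = FALSE)
  }
  beta <- unname(fit$coef[".focal"])
  se <- unname(fit$se[".focal"])
  if (is.na(beta)) {
    warning("focal term '", term, "' is aliased with the conditioning set; ",
            "no estimate", call. = FALSE)
  }
  unstable <- isTRUE(!fit$converged) || (!is.na(beta) && abs(beta) > 15)
  if (unstable) {
    warning("fit for '", term, "' is unstable (possible separation); ",
            "p-value and CI are unreliable", call. = FALSE)
  }
  p <- if (is.na(beta) || is.na(se)) NA_real_ else {
    2 * stats::pnorm(-abs(beta / se))
  }
  structure(list(
    term = term,
    beta = beta,
    se = se,
    or_ = exp(beta),
    ci95 = exp(beta + c(-1, 1) * stats::qnorm(0.975) * se),
    p = p,
    n_cases = sum(y == 1),
    n_controls = sum(y == 0),
    conditioned_on = colnames(condition) %||% character(0),
    covariates = colnames(covariates) %||% character(0),
    converged = fit$converged,
    unstable = unstable
  ), class = "hla_assoc")
}

#' @export
print.hla_assoc <- function(x, digits = 3, ...) {
  cat(sprintf(
    "%s: OR = %.3g [%.3g-%.3g], p = %.3g (n = %d/%d%s%s)\n",
    x$term, x$or_, x$ci95[1], x$ci95[2], x$p, x$n_cases, x$n_controls,
    if (length(x$conditioned_on)) {
      paste0("; conditioned on ", paste(x$conditioned_on, collapse = ", "))
    } else "",
    if (x$unstable) "; UNSTABLE" else ""
  ))
  invisible(x)
}

#' @export
as.data.frame.hla_assoc <- function(x, ...) {
  data.frame(term = x$term, beta = x$beta, se = x$se, or = x$or_,
             ci_lo = x$ci95[1], ci_hi = x$ci95[2], p = x$p,
             n_cases = x$n_cases, n_controls = x$n_controls,
             conditioned_on = paste(x$conditioned_on, collapse = ","),
             unstable = x$unstable,
             stringsAsFactors = FALSE)
}
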