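test_that("covariate-free logistic on a carrier indicator matches the
           cross-product odds ratio", {
  # carrier counts 185/397 cases vs 92/282 controls
  y <- rep(c(1, 0), c(397, 282))
  x <- c(rep(1, 185), rep(0, 212), rep(1, 92), rep(0, 190))
  fit <- fit_logistic(y, x, term = "carrier")
  expect_equal(fit$or_, oracle_cross_product_or(185, 212, 92, 190),
               tolerance = 1e-8)
  expect_equal(round(fit$or_, 2), 1.80)
  expect_equal(fit$or_, exp(fit$beta))
  expect_true(fit$ci95[1] < fit$or_ && fit$or_ < fit$ci95[2])

  # zero-variance focal term is an error, not a silent NA
  expect_error(fit_logistic(y, rep(1, length(y))), "zero variance")
  expect_error(fit_logistic(rep(1, 10), rbinom(10, 2, 0.5)),
               "both cases and controls")
})

test_that("planted effects are recovered without bias", {
  set.seed(42)
  betas <- replicate(10, {
    n <- 5000
    x <- rbinom(n, 2, 0.3)
    y <- rbinom(n, 1, plogis(-1 + 0.8 * x))
    fit_logistic(y, x)$beta
  })
  expect_lt(abs(mean(betas) - 0.8), 0.05)
})

test_that("aliased conditioning produces a warning, never a spurious p", {
  set.seed(1)
  y <- rbinom(400, 1, 0.5)
  x <- rbinom(400, 2, 0.3)
  expect_warning(res <- fit_logistic(y, x, condition = x, term = "self"),
                 "aliased")
  expect_true(is.na(res$p))
})

test_that("separation is flagged unstable rather than silently diverging", {
  y <- rep(c(1, 0), each = 50)
  x <- y  # perfect separation
  expect_warning(res <- fit_logistic(y, x), "unstable")
  expect_true(res$unstable)
})

test_that("omnibus LRT collapses to the single-term LRT when biallelic and
           is invariant to the reference residue", {
  set.seed(7)
  n <- 600
  d1 <- rbinom(n, 2, 0.3)
  d2 <- 2 - d1  # complementary residue at a biallelic position
  y <- rbinom(n, 1, plogis(-0.5 + 0.4 * d1))
  ot <- omnibus_position_test(y, cbind(A = d1, B = d2))
  expect_equal(ot$df, 1L)
  # independent single-term LRT via stats::glm
  g1 <- glm(y ~ d1, family = binomial())
  g0 <- glm(y ~ 1, family = binomial())
  lrt_p <- pchisq(g0$deviance - g1$deviance, 1, lower.tail = FALSE)
  expect_equal(ot$p, lrt_p, tolerance = 1e-8)

  # 3-residue position: statistic identical for every reference choice
  r3 <- t(rmultinom(n, 2, c(0.5, 0.3, 0.2)))
  colnames(r3) <- c("x", "y", "z")
  yy <- rbinom(n, 1, plogis(-0.5 + 0.5 * r3[, 2]))
  stats <- vapply(colnames(r3), function(ref) {
    omnibus_position_test(yy, r3, reference = ref)$stat
  }, numeric(1))
  expect_lt(max(stats) - min(stats), 1e-8)
  expect_error(omnibus_position_test(yy, r3[, 1, drop = FALSE]),
               "fit_logistic")

  # a causal residue makes the omnibus p beat a null residue's Wald p
  p_null_wald <- fit_logistic(yy, r3[, "z"])$p
  expect_lt(omnibus_position_test(yy, r3)$p, p_null_wald)
})

test_that("Wald and LRT p-values agree within a factor of two at n >= 1000", {
  set.seed(3)
  n <- 1500
  x <- rbinom(n, 2, 0.25)
  y <- rbinom(n, 1, plogis(-1 + 0.3 * x))
  wald_p <- fit_logistic(y, x)$p
  g1 <- glm(y ~ x, family = binomial())
  g0 <- glm(y ~ 1, family = binomial())
  lrt_p <- pchisq(g0$deviance - g1$deviance, 1, lower.tail = FALSE)
  expect_lt(max(wald_p / lrt_p, lrt_p / wald_p), 2)
})

test_that("scans rank a planted effect first and handle degenerate input", {
  expect_equal(nrow(assoc_scan(rbinom(10, 1, 0.5),
                               matrix(nrow = 10, ncol = 0))), 0L)
  set.seed(21)
  hits <- replicate(25, {
    n <- 1200
    X <- sapply(1:20, function(i) rbinom(n, 2, 0.3))
    colnames(X) <- sprintf("t%02d", 1:20)
    y <- rbinom(n, 1, plogis(-0.6 + 0.55 * X[, 7]))
    res <- assoc_scan(y, X)
    res$term[1] == "t07"
  })
  expect_gte(sum(hits), 22)  # planted term ranks first almost always

  # a failing term is reported and the scan continues
  X <- cbind(good = rbinom(200, 2, 0.4), flat = rep(1, 200))
  res <- assoc_scan(rbinom(200, 1, 0.5), X)
  expect_equal(nrow(res), 2L)
  expect_match(res$error[res$term == "flat"], "zero variance")
})

test_that("heterogeneity matches the closed form and an independent
           meta-analysis fit", {
  # identical effects: no heterogeneity
  h0 <- heterogeneity(c(0.5, 0.5, 0.5), c(0.1, 0.2, 0.1))
  expect_equal(h0$q, 0)
  expect_equal(h0$i2, 0)

  # hand-computed: w = 100 each, pooled = 5/6, Q = 2/3 * 100
  h <- heterogeneity(c(0.5, 0.5, 1.5), c(0.1, 0.1, 0.1))
  expect_equal(h$q, 200 / 3, tolerance = 1e-12)
  expect_equal(h$i2, (h$q - 2) / h$q * 100, tolerance = 1e-12)
  expect_true(h$i2 >= 0 && h$i2 <= 100)

  m <- metafor::rma(yi = c(0.5, 0.5, 1.5), sei = c(0.1, 0.1, 0.1),
                    method = "FE")
  expect_equal(h$q, unname(m$QE), tolerance = 1e-10)
  expect_equal(h$pooled_beta, unname(as.numeric(m$beta)), tolerance = 1e-10)

  expect_error(heterogeneity(0.5, 0.1), "2 cohorts")
})
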