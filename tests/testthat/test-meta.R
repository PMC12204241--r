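test_that("degenerate pools behave as documented", {
  # single study passes through
  p1 <- pool_random_effects(0.7, 0.2)
  expect_equal(p1$pooled_beta, 0.7)
  expect_equal(c(p1$tau2, p1$Q, p1$I2), c(0, 0, 0))
  # perfect homogeneity
  p3 <- pool_random_effects(c(0.4, 0.4, 0.4), c(0.1, 0.1, 0.1))
  expect_equal(p3$pooled_beta, 0.4)
  expect_equal(c(p3$Q, p3$tau2, p3$I2), c(0, 0, 0))
  expect_error(pool_random_effects(numeric(0), numeric(0)), "at least one")
  expect_error(pool_random_effects(c(1, 2), c(1, -1)), "positive")
})

test_that("fixed-effect pooling is the inverse-variance mean", {
  p <- pool_random_effects(c(1, 2, 3), c(1, 1, 1), method = "FE")
  expect_equal(p$pooled_beta, 2)
  expect_equal(p$se_hksj, sqrt(1 / 3))
  # unequal variances, hand-computed inverse-variance average
  b <- c(0.2, 0.8); s <- c(0.1, 0.3)
  w <- 1 / s^2
  p2 <- pool_random_effects(b, s, method = "FE")
  expect_equal(p2$pooled_beta, sum(w * b) / sum(w))
})

test_that("REML + HKSJ agrees with metafor on heterogeneous inputs", {
  skip_if_not_installed("metafor")
  cases <- list(
    list(b = c(0.3, 0.5, 0.4), s = c(0.10, 0.12, 0.11)),
    list(b = c(0.1, 0.9, 0.5), s = c(0.15, 0.20, 0.10)),
    list(b = c(-0.4, 0.6, 1.3), s = c(0.25, 0.18, 0.30)),
    list(b = c(2.0, -1.0, 0.3), s = c(0.5, 0.4, 0.6))
  )
  for (cs in cases) {
    mine <- pool_random_effects(cs$b, cs$s)
    ref <- metafor::rma(yi = cs$b, sei = cs$s, method = "REML",
                        test = "knha", control = list(tau2.max = 1e5))
    expect_equal(mine$tau2, ref$tau2, tolerance = 1e-4)
    expect_equal(mine$pooled_beta, as.numeric(ref$beta), tolerance = 1e-5)
    expect_equal(mine$se_hksj, as.numeric(ref$se), tolerance = 1e-5)
    expect_equal(mine$p_value, as.numeric(ref$pval), tolerance = 1e-4)
    expect_equal(mine$I2, as.numeric(ref$I2), tolerance = 0.5)
  }
})

test_that("heterogeneity follows the Q/I2 definitions exactly", {
  # brute-force formula evaluation
  b <- c(0, 0, 10); s <- c(1, 1, 1)
  w <- 1 / s^2
  bfe <- sum(w * b) / sum(w)
  Q_oracle <- sum(w * (b - bfe)^2)
  h <- heterogeneity(b, s)
  expect_equal(h$Q, Q_oracle)
  expect_gt(h$I2, 50)
  expect_equal(h$I2, max(0, (Q_oracle - 2) / Q_oracle) * 100)
  expect_error(heterogeneity(1, 1), "at least 2")

  # boundary algebra: Q = k-1 -> I2 = 0; Q = 2(k-1) -> I2 = 50
  expect_equal(max(0, ((2 - 2) / 2)) * 100, 0)
  k <- 3
  expect_equal((2 * (k - 1) - (k - 1)) / (2 * (k - 1)) * 100, 50)
})

test_that("pooled estimates stay inside the convex hull and ignore order", {
  withr::with_seed(8, {
    for (r in 1:20) {
      b <- rnorm(3); s <- runif(3, 0.05, 0.5)
      p <- restart_cascade(b, s)
      expect_gte(p$pooled_beta, min(b) - 1e-10)
      expect_lte(p$pooled_beta, max(b) + 1e-10)
      perm <- sample(3)
      p2 <- restart_cascade(b[perm], s[perm])
      expect_equal(p$pooled_beta, p2$pooled_beta, tolerance = 1e-10)
      expect_equal(p$tau2, p2$tau2, tolerance = 1e-10)
    }
  })
})

test_that("HKSJ is conservative relative to the normal approximation", {
  worse <- withr::with_seed(13, {
    vapply(1:1000, function(i) {
      b <- rnorm(3, 0.2, 0.1)
      s <- runif(3, 0.08, 0.12)
      p <- pool_random_effects(b, s)
      z <- p$pooled_beta / sqrt(1 / sum(1 / (s^2 + p$tau2)))
      p_norm <- 2 * stats::pnorm(-abs(z))
      p$p_value >= p_norm - 1e-12
    }, logical(1))
  })
  expect_gt(mean(worse), 0.95)
})

test_that("the restart cascade falls through REML, ML, FE", {
  ok <- restart_cascade(c(0.2, 0.3, 0.25), c(0.1, 0.1, 0.1))
  expect_equal(ok$method_used, "REML")
  # injected fitter that fails REML and ML
  stubborn <- function(beta, se, method = "REML", ...) {
    if (method %in% c("REML", "ML")) stop("no convergence")
    pool_random_effects(beta, se, method = "FE")
  }
  fe <- restart_cascade(c(1, 2, 3), c(1, 1, 1), fitter = stubborn)
  expect_equal(fe$method_used, "FE")
  expect_equal(fe$pooled_beta, 2) # inverse-variance mean, closed form
  # a fitter returning converged = FALSE also falls through
  limp <- function(beta, se, method = "REML", ...) {
    out <- pool_random_effects(beta, se, method = method)
    if (method != "FE") out$converged <- FALSE
    out
  }
  fe2 <- restart_cascade(c(1, 2, 3), c(1, 1, 1), fitter = limp)
  expect_equal(fe2$method_used, "FE")
  expect_error(restart_cascade(c(1, 2), c(1, 1), schedule = list()),
               "nonempty")
})

test_that("leave-one-out estimates match direct recomputation", {
  b <- c(0.5, 0.55, 3.0); s <- c(0.1, 0.1, 0.1)
  loo <- leave_one_out(b, s)
  expect_length(loo, 3)
  # omitting the outlier equals pooling the two concordant studies
  expect_equal(loo[3], restart_cascade(b[1:2], s[1:2])$pooled_beta)
  # k = 2: each value is the remaining estimate
  loo2 <- leave_one_out(c(0.2, 0.9), c(0.1, 0.2))
  expect_equal(loo2, c(0.9, 0.2))
  # homogeneous inputs: all LOO values equal the full pool
  b3 <- c(0.4, 0.4, 0.4)
  expect_equal(leave_one_out(b3, s), rep(0.4, 3))
})

test_that("BH adjustment matches the hand-computed step-up", {
  meta <- tibble::tibble(p_value = c(0.01, 0.02, 0.04),
                         I2 = c(0, 0, 0), signs_agree = TRUE)
  out <- adjust_and_flag(meta)
  expect_equal(out$p_adj, c(0.03, 0.03, 0.04))
  expect_true(all(out$conserved))
})

test_that("conservation requires FDR, sign agreement, and I2 strictly < 50", {
  base <- tibble::tibble(p_value = 0.001, I2 = 10, signs_agree = TRUE)
  expect_true(adjust_and_flag(base)$conserved)
  expect_false(adjust_and_flag(dplyr::mutate(base, signs_agree = FALSE))$conserved)
  expect_false(adjust_and_flag(dplyr::mutate(base, I2 = 50))$conserved)  # strict
  expect_true(adjust_and_flag(dplyr::mutate(base, I2 = 49.999))$conserved)
  expect_false(adjust_and_flag(dplyr::mutate(base, p_value = 0.9))$conserved)
})

test_that("meta_analyze pools stacked group fits into flagged rows", {
  co <- generate_cohort(15, 1, seed = 71)
  comp <- generate_composition(co, sprintf("SC%d", 1:4),
                               planted_effect("SC1", "cog_decline", 0.8),
                               seed = 72)
  fits <- fit_group_associations(comp, co, traits = "cog_decline")
  meta <- meta_analyze(fits)
  expect_equal(nrow(meta), 12) # 4 subclusters x 3 regions
  expect_true(all(meta$k == 3))
  expect_true(all(meta$I2 >= 0 & meta$I2 <= 100))
  expect_true(all(c("p_adj", "conserved", "loo_estimates") %in% names(meta)))
})
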