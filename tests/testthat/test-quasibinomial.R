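test_that("proportion normalization preserves zeros and errors on empty rows", {
  tb <- tibble::tibble(sample_id = c("s1", "s2", "s3"),
                       a = c(3, 0, 1), b = c(1, 5, 0), c = c(0, 5, 0))
  pr <- normalize_proportions(tb)
  expect_equal(pr$a, c(0.75, 0, 1))
  expect_equal(pr$b, c(0.25, 0.5, 0))
  expect_equal(pr$c, c(0, 0.5, 0))
  expect_equal(pr$total, c(4, 10, 1))
  expect_error(normalize_proportions(tibble::tibble(a = 0, b = 0)),
               "positive total")
  one <- normalize_proportions(tibble::tibble(a = c(2, 7)))
  expect_equal(one$a, c(1, 1))
})

test_that("binary two-group fit equals the saturated logit closed form", {
  d <- make_fit_data(n = 40, seed = 1)
  d$g <- rep(c(0, 1), 20)
  fit <- fit_quasibinomial(d, "y", "g", covariates = character(0))
  p1 <- sum(d$total[d$g == 1] * d$y[d$g == 1]) / sum(d$total[d$g == 1])
  p0 <- sum(d$total[d$g == 0] * d$y[d$g == 0]) / sum(d$total[d$g == 0])
  expect_equal(fit$beta_hat, qlogis(p1) - qlogis(p0), tolerance = 1e-8)

  # symmetric null: identical weighted means in the two groups -> beta 0
  d2 <- data.frame(y = c(0.5, 0.5, 0.5, 0.5), g = c(0, 0, 1, 1),
                   total = c(100, 200, 150, 50))
  f2 <- fit_quasibinomial(d2, "y", "g", covariates = character(0))
  expect_equal(f2$beta_hat, 0, tolerance = 1e-10)
})

test_that("IRLS coefficients match an independent numerical maximizer", {
  withr::with_seed(99, {
    for (r in 1:10) {
      d <- make_fit_data(n = 50, seed = 100 + r, beta = runif(1, -1, 1),
                         p0 = runif(1, 0.1, 0.5))
      fit <- fit_quasibinomial(d, "y", "x")
      X <- cbind(1, d$x, d$age_at_death, as.numeric(d$sex == "M"), d$pmi)
      b_opt <- oracle_logit_mle(X, d$y, d$total)
      expect_equal(unname(fit$coefficients$estimate), unname(b_opt),
                   tolerance = 1e-6)
    }
  })
})

test_that("robust covariance matches the sandwich package for every HC type", {
  d <- make_fit_data(n = 45, seed = 7, beta = 0.4)
  g <- glm(y ~ x + age_at_death + sex + pmi, family = quasibinomial,
           weights = total, data = d)
  for (hc in c("HC0", "HC1", "HC3")) {
    fit <- fit_quasibinomial(d, "y", "x", hc_type = hc)
    V <- sandwich::vcovHC(g, type = hc)
    expect_equal(unname(fit$robust_se), unname(sqrt(diag(V))[2]),
                 tolerance = 1e-6, label = hc)
  }
  # model-based quantities match glm too
  expect_equal(fit_quasibinomial(d, "y", "x")$dispersion_phi,
               summary(g)$dispersion, tolerance = 1e-6)
})

test_that("sandwich covariance is symmetric PSD and CIs bracket the estimate", {
  withr::with_seed(11, {
    for (r in 1:5) {
      d <- make_fit_data(n = 35, seed = 200 + r, beta = rnorm(1, 0, 0.5))
      fit <- fit_quasibinomial(d, "y", "x")
      V <- fit$vcov
      expect_equal(V, t(V))
      expect_true(all(eigen(V, symmetric = TRUE)$values > -1e-10))
      expect_lt(fit$ci_low, fit$beta_hat)
      expect_gt(fit$ci_high, fit$beta_hat)
      expect_equal(fit$p_value,
                   2 * pt(-abs(fit$t_stat), fit$n_samples - 5))
    }
  })
})

test_that("dispersion is recovered near 1 on pure binomial data", {
  phis <- vapply(1:20, function(r) {
    d <- make_fit_data(n = 200, seed = 300 + r)
    fit_quasibinomial(d, "y", "x")$dispersion_phi
  }, numeric(1))
  expect_gt(median(phis), 0.9)
  expect_lt(median(phis), 1.1)
})

test_that("robust and model-based SEs agree under homoskedasticity", {
  # equal denominators => the binomial weight model is correctly specified
  rel <- vapply(1:10, function(r) {
    d <- make_fit_data(n = 200, seed = 400 + r)
    d$total <- rep(2000, 200)
    d$y <- withr::with_seed(500 + r, rbinom(200, 2000, 0.25) / 2000)
    fit <- fit_quasibinomial(d, "y", "x", hc_type = "HC0")
    g <- glm(y ~ x + age_at_death + sex + pmi, family = quasibinomial,
             weights = total, data = d)
    fit$robust_se / summary(g)$coefficients[2, 2]
  }, numeric(1))
  expect_lt(abs(median(rel) - 1), 0.1)
})

test_that("translation of a covariate changes only the intercept", {
  d <- make_fit_data(n = 60, seed = 21, beta = 0.3)
  f1 <- fit_quasibinomial(d, "y", "x")
  d2 <- d
  d2$age_at_death <- d2$age_at_death + 100
  f2 <- fit_quasibinomial(d2, "y", "x")
  expect_equal(f1$beta_hat, f2$beta_hat, tolerance = 1e-6)
  expect_equal(f1$robust_se, f2$robust_se, tolerance = 1e-6)
  expect_false(isTRUE(all.equal(
    f1$coefficients$estimate[1], f2$coefficients$estimate[1])))
})

test_that("rank-deficient designs error; proportions outside [0,1] error", {
  d <- make_fit_data(n = 30, seed = 5)
  d$dup <- d$x
  expect_error(
    fit_quasibinomial(d, "y", "x", covariates = c("dup", "age_at_death")),
    "rank deficient")
  d$y[1] <- 1.5
  expect_error(fit_quasibinomial(d, "y", "x"), "\\[0, 1\\]")
})

test_that("tidy and glance return the documented shapes", {
  fit <- fit_quasibinomial(make_fit_data(n = 40, seed = 2), "y", "x")
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 5)
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_true(all(c("beta_hat", "robust_se", "dispersion_phi",
                    "converged") %in% names(gl)))
})

test_that("eligibility requires one more sample than model terms", {
  mk <- function(n) {
    tibble::tibble(sample_id = as.character(seq_len(n)),
                   s1 = rep(0.5, n), total = rep(100, n),
                   voi = rnorm(n), age_at_death = rnorm(n),
                   sex = rep(c("F", "M"), length.out = n), pmi = rnorm(n),
                   education = rnorm(n))
  }
  path_cov <- c("age_at_death", "sex", "pmi")
  # pathological model: 5 terms -> needs >= 6 samples
  expect_equal(eligible_subclusters(mk(6)["s1"], mk(6), "voi", path_cov), "s1")
  expect_length(eligible_subclusters(mk(5)["s1"], mk(5), "voi", path_cov), 0)
  # cognitive model adds education: 6 terms -> needs >= 7
  cog_cov <- c(path_cov, "education")
  expect_length(eligible_subclusters(mk(6)["s1"], mk(6), "voi", cog_cov), 0)
  expect_equal(eligible_subclusters(mk(7)["s1"], mk(7), "voi", cog_cov), "s1")
})

test_that("group association driver fits only composition columns", {
  co <- generate_cohort(8, 1, seed = 31)
  comp <- generate_composition(co, sprintf("SC%d", 1:4), seed = 32)
  fits <- fit_group_associations(comp, co, traits = "cog_decline")
  expect_setequal(unique(fits$subcluster), sprintf("SC%d", 1:4))
  expect_setequal(unique(fits$group), c("AA-NL", "L", "W-NL"))
  expect_true(all(fits$n_samples == 8))
  expect_true(all(fits$converged))
})

test_that("permutation calibration is deterministic and null-calibrated", {
  co <- generate_cohort(30, 1, seed = 61)
  comp <- generate_composition(co, sprintf("SC%d", 1:4), seed = 62)
  pr <- normalize_proportions(comp)
  d <- dplyr::left_join(pr, dplyr::select(co, -regions), by = "donor_id")
  d <- d[d$group == "L" & d$region == "DLPFC", ]
  cal <- permutation_calibration(d, "SC1", "cog_decline", n_perm = 400,
                                 seed = 9)
  cal2 <- permutation_calibration(d, "SC1", "cog_decline", n_perm = 400,
                                  seed = 9)
  expect_identical(cal$p_values, cal2$p_values)
  r05 <- cal$rates$empirical_rate[cal$rates$alpha == 0.05]
  # 3-SD binomial band around 0.05 at 400 permutations
  expect_gt(r05, 0.05 - 3 * sqrt(0.05 * 0.95 / 400))
  expect_lt(r05, 0.05 + 3 * sqrt(0.05 * 0.95 / 400))

  # constant response: slope exactly 0, never rejected
  d$flat <- 0.5
  calc <- permutation_calibration(d, "flat", "cog_decline", n_perm = 100,
                                  seed = 2)
  expect_equal(sum(calc$p_values < 0.05, na.rm = TRUE), 0)
  expect_error(permutation_calibration(d, "SC1", "cog_decline", n_perm = 50),
               "100")
})
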