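# Random-effects pooling across population groups.
#
# tau^2 is estimated by REML Fisher scoring on the profiled restricted
# likelihood (analytic gradient, floor at zero); the pooled coefficient is
# the inverse-variance-weighted mean with weights 1/(se_i^2 + tau^2); the
# Hartung-Knapp-Sidik-Jonkman adjustment rescales its variance by
# q = sum w_i (b_i - pooled)^2 / (k - 1) and tests on k - 1 df.

reml_tau2 <- function(beta, v, method = c("REML", "ML"), max_iter = 50,
                      step = 1, tol = 1e-10) {
  method <- match.arg(method)
  k <- length(beta)
  tau2 <- max(0, var(beta) - mean(v)) # DerSimonian-Laird-flavored start
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    w <- 1 / (v + tau2)
    bw <- sum(w * beta) / sum(w)
    r2 <- (beta - bw)^2
    if (method == "REML") {
      score <- 0.5 * (sum(w^2 * r2) - sum(w) + sum(w^2) / sum(w))
      info <- 0.5 * (sum(w^2) - 2 * sum(w^3) / sum(w) +
                       (sum(w^2) / sum(w))^2)
    } else {
      score <- 0.5 * (sum(w^2 * r2) - sum(w))
      info <- 0.5 * sum(w^2)
    }
    if (!is.finite(score) || !is.finite(info) || info <= 0) break
    delta <- step * score / info
    tau2_new <- max(0, tau2 + delta)
    if (abs(tau2_new - tau2) < tol * (1 + tau2)) {
      tau2 <- tau2_new
      converged <- TRUE
      break
    }
    tau2 <- tau2_new
  }
  list(tau2 = tau2, converged = converged, iter = it)
}

#' Cochran heterogeneity
#'
#' Cochran's Q under fixed-effect weights and the derived I^2 statistic
#' (`I2 = max(0, (Q - (k-1))/Q) * 100`, defined as 0 when `Q = 0`).
#'
#' @param beta,se Per-group estimates and their standard errors (k >= 2).
#' @return List with `Q` and `I2` (percent).
#' @export
#' @examples
#' heterogeneity(c(0, 0, 10), c(1, 1, 1))
heterogeneity <- function(beta, se) {
  k <- length(beta)
  if (k < 2) abort("Heterogeneity needs at least 2 estimates.")
  if (any(se <= 0)) abort("Standard errors must be positive.")
  w <- 1 / se^2
  b_fe <- sum(w * beta) / sum(w)
  Q <- sum(w * (beta - b_fe)^2)
  I2 <- if (Q <= 0) 0 else max(0, (Q - (k - 1)) / Q) * 100
  list(Q = Q, I2 = I2)
}

#' Pool per-group estimates with a random-effects meta-analysis
#'
#' @param beta Per-group coefficient estimates.
#' @param se Their (robust) standard errors, all positive.
#' @param method `"REML"` (default), `"ML"`, or `"FE"` (tau^2 fixed at 0
#'   with a plain inverse-variance t-test).
#' @param truncate_hksj Apply the `max(q, 1)` truncation to the HKSJ
#'   variance ratio (default `FALSE`, the cited method's default; the
#'   untruncated form can yield `se_hksj` below the conventional
#'   random-effects SE).
#' @param max_iter,step Fisher-scoring iteration cap and step damping for
#'   the tau^2 estimation.
#' @return Object of class `meta_pool`: `pooled_beta`, `tau2`, `Q`, `I2`,
#'   `se_hksj`, `t_stat`, `p_value`, `ci_low`, `ci_high`, `k`,
#'   `method_used`, `converged`. For `k = 1` the single estimate is passed
#'   through with `tau2 = Q = I2 = 0`.
#' @export
#' @examples
#' pool_random_effects(c(0.3, 0.5, 0.4), c(0.1, 0.12, 0.11))
pool_random_effects <- function(beta, se, method = c("REML", "ML", "FE"),
                                truncate_hksj = FALSE, max_iter = 50,
                                step = 1) {
  method <- match.arg(method)
  k <- length(beta)
  if (k == 0) abort("Need at least one estimate.")
  if (length(se) != k || any(!is.finite(se)) || any(se <= 0)) {
    abort("`se` must be positive and match `beta` in length.")
  }
  v <- se^2

  if (k == 1) {
    return(structure(list(
      pooled_beta = beta, tau2 = 0, Q = 0, I2 = 0, se_hksj = se,
      t_stat = NA_real_, p_value = NA_real_,
      ci_low = NA_real_, ci_high = NA_real_, k = 1L,
      method_used = "FE", converged = TRUE, weights = 1
    ), class = "meta_pool"))
  }

  if (method == "FE") {
    tau2 <- 0
    converged <- TRUE
    w <- 1 / v
    pooled <- sum(w * beta) / sum(w)
    se_p <- sqrt(1 / sum(w))
  } else {
    est <- reml_tau2(beta, v, method, max_iter = max_iter, step = step)
    tau2 <- est$tau2
    converged <- est$converged
    w <- 1 / (v + tau2)
    pooled <- sum(w * beta) / sum(w)
    # HKSJ variance
    q <- sum(w * (beta - pooled)^2) / (k - 1)
    if (truncate_hksj) q <- max(q, 1)
    se_p <- sqrt(q / sum(w))
    if (se_p == 0) se_p <- sqrt(1 / sum(w)) * 1e-8 # all-identical degenerate
  }
  if (method == "FE") {
    tstat <- pooled / se_p
  } else {
    tstat <- pooled / se_p
  }
  df <- k - 1
  pval <- 2 * pt(-abs(tstat), df)
  crit <- qt(0.975, df)
  het <- heterogeneity(beta, se)

  structure(list(
    pooled_beta = pooled, tau2 = tau2, Q = het$Q, I2 = het$I2,
    se_hksj = se_p, t_stat = tstat, p_value = pval,
    ci_low = pooled - crit * se_p, ci_high = pooled + crit * se_p,
    k = k, method_used = method, converged = converged, weights = w
  ), class = "meta_pool")
}

#' @export
print.meta_pool <- function(x, ...) {
  cat(sprintf(
    "Random-effects pool (%s, k=%d): beta = %.4f [%.4f, %.4f], p = %.3g\n",
    x$method_used, x$k, x$pooled_beta, x$ci_low, x$ci_high, x$p_value))
  cat(sprintf("  tau2 = %.4g, Q = %.3f, I2 = %.1f%%\n", x$tau2, x$Q, x$I2))
  invisible(x)
}

#' @rdname tidy
#' @export
tidy.meta_pool <- function(x, ...) {
  tibble(pooled_beta = x$pooled_beta, se_hksj = x$se_hksj,
         ci_low = x$ci_low, ci_high = x$ci_high,
         t_stat = x$t_stat, p_value = x$p_value)
}

#' @rdname tidy
#' @export
glance.meta_pool <- function(x, ...) {
  tibble(tau2 = x$tau2, Q = x$Q, I2 = x$I2, k = x$k,
         method_used = x$method_used, converged = x$converged)
}

#' Pool with the restart and fallback cascade
#'
#' Attempts REML with default settings; on non-convergence retries with
#' progressively larger iteration caps and damped steps, then falls back to
#' ML, and finally to a fixed-effects pool with a t-test (which always
#' succeeds). `method_used` on the result records the first method that
#' converged.
#'
#' @inheritParams pool_random_effects
#' @param schedule List of `list(max_iter=, step=)` REML retry settings
#'   (default doubles the cap and halves the step twice).
#' @param fitter Pooling engine, interface-compatible with
#'   [pool_random_effects()] (injectable for testing the cascade).
#' @return A `meta_pool` object.
#' @export
restart_cascade <- function(beta, se,
                            schedule = list(list(max_iter = 50, step = 1),
                                            list(max_iter = 100, step = 0.5),
                                            list(max_iter = 200, step = 0.25)),
                            truncate_hksj = FALSE,
                            fitter = pool_random_effects) {
  if (!length(schedule)) abort("`schedule` must be nonempty.")
  for (s in schedule) {
    fit <- tryCatch(
      fitter(beta, se, method = "REML", truncate_hksj = truncate_hksj,
             max_iter = s$max_iter, step = s$step),
      error = function(e) NULL
    )
    if (!is.null(fit) && isTRUE(fit$converged)) return(fit)
  }
  fit <- tryCatch(
    fitter(beta, se, method = "ML", truncate_hksj = truncate_hksj),
    error = function(e) NULL
  )
  if (!is.null(fit) && isTRUE(fit$converged)) return(fit)
  fitter(beta, se, method = "FE", truncate_hksj = truncate_hksj)
}

#' Leave-one-out pooled estimates
#'
#' @inheritParams pool_random_effects
#' @param ... Passed to [restart_cascade()].
#' @return Numeric vector: element i is the pooled estimate omitting study
#'   i (for k = 2 each value is simply the remaining estimate).
#' @export
leave_one_out <- function(beta, se, ...) {
  k <- length(beta)
  if (k < 2) abort("Leave-one-out needs at least 2 estimates.")
  vapply(seq_len(k), function(i) {
    restart_cascade(beta[-i], se[-i], ...)$pooled_beta
  }, numeric(1))
}

#' Meta-analyze stacked per-group fits and flag conserved associations
#'
#' Takes the stacked output of [fit_group_associations()] (all three
#' population groups), pools each (region, subcluster, trait) cell with the
#' REML/HKSJ cascade, computes heterogeneity and leave-one-out estimates,
#' applies Benjamini-Hochberg correction across the full result family, and
#' flags an association as conserved when the adjusted p-value is below
#' `alpha`, the per-group coefficient signs all agree, and I^2 is strictly
#' below `i2_max`.
#'
#' @param fits Tibble from [fit_group_associations()]; the BH family is all
#'   rows pooled here (non-eligible subclusters are simply absent).
#' @param alpha FDR level (default 0.05).
#' @param i2_max I^2 ceiling, percent (default 50; strict inequality).
#' @param response_col Column naming the modeled unit (default
#'   `"subcluster"`; pass `"factor_id"` for factor associations).
#' @param ... Passed to [restart_cascade()].
#' @return Tibble with one row per (region, unit, trait): pooled fields
#'   (`pooled_beta`, `tau2`, `Q`, `I2`, `se_hksj`, `t_stat`, `p_value`,
#'   `method_used`, `k`), per-group estimates in list-columns
#'   (`group_betas`, `group_ses`, `loo_estimates`), `signs_agree`, `p_adj`,
#'   `conserved`.
#' @export
meta_analyze <- function(fits, alpha = 0.05, i2_max = 50,
                         response_col = "subcluster", ...) {
  stopifnot(all(c("group", "region", response_col, "trait",
                  "beta_hat", "robust_se") %in% names(fits)))
  grouped <- dplyr::group_by(fits, region,
                             !!rlang::sym(response_col), trait)
  out <- dplyr::group_modify(grouped, function(d, key) {
    b <- d$beta_hat; s <- d$robust_se
    ok <- is.finite(b) & is.finite(s) & s > 0
    b <- b[ok]; s <- s[ok]
    if (!length(b)) return(tibble())
    pool <- restart_cascade(b, s, ...)
    loo <- if (length(b) >= 2) list(leave_one_out(b, s, ...)) else list(NA_real_)
    tibble(
      pooled_beta = pool$pooled_beta, tau2 = pool$tau2,
      Q = pool$Q, I2 = pool$I2, se_hksj = pool$se_hksj,
      t_stat = pool$t_stat, p_value = pool$p_value,
      method_used = pool$method_used, k = pool$k,
      signs_agree = length(unique(sign(b))) == 1L,
      group_betas = list(setNames(b, d$group[ok])),
      group_ses = list(setNames(s, d$group[ok])),
      loo_estimates = loo
    )
  })
  out <- dplyr::ungroup(out)
  adjust_and_flag(out, alpha = alpha, i2_max = i2_max)
}

#' Benjamini-Hochberg adjustment and conservation flags
#'
#' Applies BH step-up across all rows present (the full family of attempted
#' pools) and sets the `conserved` flag: `p_adj < alpha` AND all per-group
#' signs equal AND `I2 < i2_max` (strict).
#'
#' @param meta Tibble with columns `p_value`, `I2`, `signs_agree`.
#' @param alpha,i2_max See [meta_analyze()].
#' @return `meta` with `p_adj` and `conserved` columns.
#' @export
adjust_and_flag <- function(meta, alpha = 0.05, i2_max = 50) {
  meta$p_adj <- p.adjust(meta$p_value, method = "BH")
  meta$conserved <- !is.na(meta$p_adj) & meta$p_adj < alpha &
    meta$signs_agree & meta$I2 < i2_max
  meta
}
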