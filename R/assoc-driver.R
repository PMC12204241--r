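#' Default AD trait specification
#'
#' The phenotype panel modeled throughout the package, with the covariate
#' rule (education is added for cognition-related traits) and the contrast
#' coding used for the categorical staging variables: CERAD 1-2 (definite or
#' probable AD) versus 3-4, Braak 3+ versus 0-2, and clinical diagnosis
#' coded as cognitively impaired (MCI or AD) versus NCI. The map is a plain
#' tibble, so alternative contrasts are a `mutate()` away.
#'
#' @return Tibble with columns `trait` (model column to use), `source`
#'   (cohort column it derives from), `cognitive` (adds education as a
#'   covariate when `TRUE`).
#' @export
default_trait_spec <- function() {
  tibble(
    trait = c("cerad_ad", "braak_high", "neuritic_plaques",
              "diffuse_plaques", "amyloid_sqrt", "tangles_sqrt",
              "dx_impaired", "cog_decline"),
    source = c("cerad", "braak", "neuritic_plaques", "diffuse_plaques",
               "amyloid_sqrt", "tangles_sqrt", "clinical_dx", "cog_decline"),
    cognitive = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE)
  )
}

# Materialize contrast-coded trait columns on a sample/cohort table.
add_trait_contrasts <- function(data) {
  if ("cerad" %in% names(data)) data$cerad_ad <- as.numeric(data$cerad <= 2)
  if ("braak" %in% names(data)) data$braak_high <- as.numeric(data$braak >= 3)
  if ("clinical_dx" %in% names(data)) {
    data$dx_impaired <- as.numeric(data$clinical_dx %in% c("MCI", "AD"))
  }
  data
}

#' Which subclusters are eligible for a model?
#'
#' A subcluster is modeled only when the number of samples with complete
#' response and covariate data is at least one more than the number of model
#' terms (intercept + variable of interest + covariates, sex counting as one
#' term, education included only for cognitive traits).
#'
#' @param counts Composition tibble (counts or proportions; only
#'   completeness matters).
#' @param data Sample-level covariate table aligned to `counts` rows (pass
#'   the joined table if they already share rows).
#' @param trait,covariates Model terms (see [fit_quasibinomial()]).
#' @return Character vector of eligible subcluster column names.
#' @export
eligible_subclusters <- function(counts, data = counts, trait,
                                 covariates = c("age_at_death", "sex", "pmi")) {
  id_cols <- intersect(c("sample_id", "donor_id", "region", "total"),
                       names(counts))
  subs <- setdiff(names(counts)[vapply(counts, is.numeric, logical(1))],
                  id_cols)
  n_terms <- 2L + length(covariates)
  ok_cov <- complete.cases(as.data.frame(data)[c(trait, covariates)])
  keep <- vapply(subs, function(s) {
    sum(ok_cov & !is.na(counts[[s]])) >= n_terms + 1L
  }, logical(1))
  subs[keep]
}

#' Fit all per-group subcluster-by-trait proportion models
#'
#' The stratified first stage: for every population group, region, eligible
#' subcluster and trait, fits the quasibinomial robust model of the
#' within-class proportion on the trait plus covariates (age at death, sex,
#' PMI, and education for cognitive traits). Output feeds
#' [meta_analyze()] unchanged.
#'
#' @param composition Composition counts tibble from
#'   [generate_composition()] (or the same shape).
#' @param cohort Donor table from [generate_cohort()].
#' @param traits Trait specification tibble (default
#'   [default_trait_spec()]); a character vector of numeric cohort columns
#'   is also accepted (treated as non-cognitive).
#' @param regions Regions to fit (default: all present).
#' @param covariates Base covariates.
#' @param ... Passed to [fit_quasibinomial()] (`weighted`, `hc_type`, ...).
#' @return Tibble with one row per (group, region, subcluster, trait) fit
#'   and columns `beta_hat`, `robust_se`, `ci_low`, `ci_high`, `t_stat`,
#'   `p_value`, `dispersion_phi`, `n_samples`, `converged`.
#' @export
fit_group_associations <- function(composition, cohort,
                                   traits = default_trait_spec(),
                                   regions = NULL,
                                   covariates = c("age_at_death", "sex", "pmi"),
                                   ...) {
  if (is.character(traits)) {
    traits <- tibble(trait = traits, source = traits, cognitive = FALSE)
  }
  id_cols <- intersect(c("sample_id", "donor_id", "region", "total"),
                       names(composition))
  subcluster_cols <- setdiff(
    names(composition)[vapply(composition, is.numeric, logical(1))], id_cols)
  props <- normalize_proportions(composition)
  donor_cols <- setdiff(names(cohort), c("regions"))
  data <- dplyr::left_join(props, cohort[donor_cols], by = "donor_id")
  data <- add_trait_contrasts(data)
  regions <- regions %||% unique(data$region)
  groups <- levels(factor(data$group))

  grid <- tidyr::expand_grid(group = groups, region = regions,
                             trait_row = seq_len(nrow(traits)))
  purrr::pmap_dfr(grid, function(group, region, trait_row) {
    tr <- traits$trait[trait_row]
    cov <- c(covariates, if (traits$cognitive[trait_row]) "education")
    sub_data <- data[data$group == group & data$region == region, ,
                     drop = FALSE]
    if (!nrow(sub_data) || !tr %in% names(sub_data)) return(NULL)
    subs <- eligible_subclusters(sub_data[c(id_cols, subcluster_cols)],
                                 sub_data, tr, cov)
    purrr::map_dfr(subs, function(s) {
      fit <- tryCatch(
        fit_quasibinomial(sub_data, response = s, trait = tr,
                          covariates = cov, ...),
        error = function(e) NULL
      )
      if (is.null(fit)) return(NULL)
      dplyr::bind_cols(
        tibble(group = group, region = region, subcluster = s, trait = tr),
        glance(fit)
      )
    })
  })
}

#' Permutation calibration of the proportion model
#'
#' Shuffles the (proportion, denominator) pairs across samples within a
#' group, refits the model for each permutation, and reports the fraction of
#' permuted fits rejecting at each alpha: an empirical check that the
#' quasibinomial robust pipeline holds its nominal false-positive rate on
#' the data at hand.
#'
#' @inheritParams fit_quasibinomial
#' @param n_perm Number of permutations (>= 100).
#' @param alphas Nominal levels to report.
#' @param seed Integer seed (permutation order is deterministic given it).
#' @return List of class `qb_calibration`: `rates` (tibble `alpha`,
#'   `empirical_rate`), `p_values` (length `n_perm`), `n_perm`.
#' @export
permutation_calibration <- function(data, response, trait,
                                    covariates = c("age_at_death", "sex", "pmi"),
                                    denominator = "total", n_perm = 1000,
                                    alphas = c(0.01, 0.05, 0.1), seed = 1,
                                    ...) {
  if (n_perm < 100) abort("`n_perm` must be at least 100.")
  data <- as.data.frame(data)
  ps <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      idx <- sample(nrow(data))
      perm <- data
      perm[[response]] <- data[[response]][idx]
      if (denominator %in% names(data)) {
        perm[[denominator]] <- data[[denominator]][idx]
      }
      fit <- tryCatch(
        fit_quasibinomial(perm, response, trait, covariates,
                          denominator = denominator, ...),
        error = function(e) NULL
      )
      if (is.null(fit)) NA_real_ else fit$p_value
    }, numeric(1))
  })
  rates <- tibble(
    alpha = alphas,
    empirical_rate = vapply(alphas, function(a) mean(ps < a, na.rm = TRUE),
                            numeric(1))
  )
  structure(list(rates = rates, p_values = ps, n_perm = n_perm),
            class = "qb_calibration")
}

#' @export
print.qb_calibration <- function(x, ...) {
  cat("Permutation calibration (", x$n_perm, " permutations)\n", sep = "")
  print(x$rates)
  invisible(x)
}
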