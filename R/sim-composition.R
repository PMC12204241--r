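#' Declare a planted compositional effect
#'
#' Ground truth for parameter-recovery tests: a per-group log-odds slope
#' linking one subcluster's within-class proportion to one phenotype.
#'
#' @param subcluster Subcluster label the effect acts on.
#' @param phenotype Phenotype column name in the cohort (e.g.
#'   `"cog_decline"`).
#' @param beta Numeric vector of length 3 (or 1, recycled): log-odds slope
#'   in each population group, ordered `AA-NL`, `L`, `W-NL`.
#' @return A tibble with columns `subcluster`, `phenotype`, `group`, `beta`.
#' @export
#' @examples
#' planted_effect("SC2", "cog_decline", 0.5)
planted_effect <- function(subcluster, phenotype, beta) {
  if (!length(beta) %in% c(1L, 3L)) {
    abort("`beta` must have length 1 or 3.")
  }
  tibble(
    subcluster = subcluster, phenotype = phenotype,
    group = factor(POP_GROUPS, levels = POP_GROUPS),
    beta = rep_len(beta, 3L)
  )
}

#' Simulate per-sample subcluster nucleus counts within one broad class
#'
#' Draws, for every profiled (donor, region) sample, a Dirichlet-multinomial
#' vector of nucleus counts across the subclusters of a broad cell class.
#' The baseline composition on the log-odds (softmax) scale is shifted for
#' each planted effect by `beta[group] * phenotype_value`, so a fitted
#' logistic slope for the target subcluster recovers `beta` (other
#' subclusters' logits do not depend on the phenotype). Overdispersion
#' relative to the multinomial is controlled by `concentration` (Dirichlet
#' precision; larger = less overdispersed; `Inf` gives pure multinomial).
#'
#' @param cohort Tibble from [generate_cohort()].
#' @param subclusters Character vector of subcluster labels (>= 2).
#' @param effects Planted effects: a tibble from [planted_effect()] (rows
#'   may be bound together), or `NULL` for a pure null.
#' @param total_nuclei Median nuclei per sample; totals are drawn
#'   log-normal around it (sdlog 0.5).
#' @param concentration Dirichlet precision (> 0, default 50); `Inf` for
#'   multinomial sampling.
#' @param baseline Optional baseline proportion simplex (length of
#'   `subclusters`). Default: a fixed, mildly skewed simplex.
#' @param broad_class Label stored on the result.
#' @param seed Integer seed.
#' @return A tibble with columns `sample_id`, `donor_id`, `region`, `total`,
#'   and one count column per subcluster. Attributes: `"broad_class"`,
#'   `"subclusters"`, `"truth"` (baseline and effects).
#' @export
generate_composition <- function(cohort, subclusters, effects = NULL,
                                 total_nuclei = 5000, concentration = 50,
                                 baseline = NULL, broad_class = "class",
                                 seed = 1) {
  assert_positive_scalar(total_nuclei, "total_nuclei")
  if (!(is.numeric(concentration) && length(concentration) == 1L &&
        concentration > 0)) {
    abort("`concentration` must be a single positive number (Inf allowed).")
  }
  K <- length(subclusters)
  if (K < 2) abort("Need at least 2 subclusters.")
  if (!is.null(effects)) {
    bad <- setdiff(unique(effects$subcluster), subclusters)
    if (length(bad)) {
      abort(sprintf("Unknown subcluster in `effects`: %s",
                    paste(bad, collapse = ", ")))
    }
    for (v in unique(effects$phenotype)) {
      if (!v %in% names(cohort)) {
        abort(sprintf("Phenotype `%s` not found in cohort.", v))
      }
    }
  }
  if (is.null(baseline)) {
    baseline <- softmax(seq(0.8, -0.8, length.out = K))
  }
  if (length(baseline) != K || any(baseline <= 0)) {
    abort("`baseline` must be a positive simplex matching `subclusters`.")
  }
  baseline <- baseline / sum(baseline)

  samples <- cohort_samples(cohort)
  n <- nrow(samples)

  with_seed(seed, {
    totals <- pmax(50, round(rlnorm(n, log(total_nuclei), 0.5)))
    eta0 <- log(baseline)
    counts <- matrix(0L, n, K, dimnames = list(samples$sample_id, subclusters))
    for (i in seq_len(n)) {
      eta <- eta0
      if (!is.null(effects) && nrow(effects)) {
        eff_i <- effects[effects$group == as.character(samples$group[i]), ,
                         drop = FALSE]
        if (nrow(eff_i)) {
          for (j in seq_len(nrow(eff_i))) {
            x <- as.numeric(samples[[eff_i$phenotype[j]]][i])
            s <- match(eff_i$subcluster[j], subclusters)
            eta[s] <- eta[s] + eff_i$beta[j] * x
          }
        }
      }
      p <- softmax(eta)
      if (is.finite(concentration)) {
        p <- rdirichlet(concentration * p)
      }
      counts[i, ] <- as.integer(rmultinom(1, totals[i], p))
    }
    out <- dplyr::bind_cols(
      samples[c("sample_id", "donor_id", "region")],
      tibble(total = totals),
      as_tibble(counts)
    )
    attr(out, "broad_class") <- broad_class
    attr(out, "subclusters") <- subclusters
    attr(out, "truth") <- list(baseline = setNames(baseline, subclusters),
                               effects = effects)
    out
  })
}

#' Simulate donors with planted molecular subgroup structure
#'
#' Generates donor-level within-class proportion profiles from `n_groups`
#' distinct Dirichlet baselines, as ground truth for donor-subgrouping
#' recovery tests. Baselines are fixed, well-separated simplexes (each
#' subgroup up-weights its own block of subclusters).
#'
#' @param n_per_subgroup Donors per planted subgroup.
#' @param n_groups Number of planted subgroups (default 3).
#' @param n_subclusters Number of proportion features (default 8).
#' @param concentration Dirichlet precision of donor-level noise around the
#'   subgroup baseline (default 50).
#' @param separation Log-odds offset distinguishing each subgroup's
#'   signature subclusters (default 1).
#' @param seed Integer seed.
#' @return A list: `features` (tibble, `donor_id` + proportion columns) and
#'   `truth` (tibble `donor_id`, `subgroup`).
#' @export
generate_subgroup_profiles <- function(n_per_subgroup, n_groups = 3,
                                       n_subclusters = 8,
                                       concentration = 50, separation = 1,
                                       seed = 1) {
  if (n_subclusters < n_groups) abort("Need >= one subcluster per subgroup.")
  blocks <- split(seq_len(n_subclusters),
                  rep(seq_len(n_groups), length.out = n_subclusters))
  with_seed(seed, {
    n <- n_per_subgroup * n_groups
    subgroup <- rep(seq_len(n_groups), each = n_per_subgroup)
    donor_id <- sprintf("S%03d", seq_len(n))
    X <- matrix(0, n, n_subclusters,
                dimnames = list(donor_id,
                                sprintf("SC%02d", seq_len(n_subclusters))))
    for (g in seq_len(n_groups)) {
      eta <- rep(0, n_subclusters)
      eta[blocks[[g]]] <- separation
      base <- softmax(eta)
      for (i in which(subgroup == g)) {
        X[i, ] <- rdirichlet(concentration * base)
      }
    }
    list(
      features = dplyr::bind_cols(tibble(donor_id = donor_id), as_tibble(X)),
      truth = tibble(donor_id = donor_id, subgroup = subgroup)
    )
  })
}
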