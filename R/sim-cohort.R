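#' Simulate a multi-population autopsy cohort
#'
#' Generates donors from the three self-identified population groups used
#' throughout the package (`"AA-NL"`, `"L"`, `"W-NL"`), with demographic
#' covariates (age at death, sex, post-mortem interval, education), a latent
#' disease-severity variable, and the derived Alzheimer's disease phenotypes:
#' CERAD score (1 = Definite AD ... 4 = No AD), Braak stage (0-6),
#' SD-scaled neuritic and diffuse plaque counts, square-root amyloid load and
#' tangle density, clinical diagnosis (NCI/MCI/AD), and the negated
#' person-specific slope of cognitive decline (higher = steeper decline).
#' Each donor carries a set of profiled brain regions (DLPFC, STG, AC);
#' region coverage is incomplete when `region_coverage < 1`, mimicking real
#' banked-tissue availability, with at least one region guaranteed.
#'
#' Severity correlations: Braak, CERAD, plaque/tangle measures, clinical
#' diagnosis and cognitive decline are all monotone functions of one shared
#' latent severity draw plus independent noise, so phenotypes are mutually
#' correlated the way staging variables are in an aging cohort.
#'
#' @param n_per_group Number of donors in each of the three population
#'   groups (single integer, >= 2).
#' @param region_coverage Probability that each of the three regions was
#'   profiled for a donor, in (0, 1]. Donors drawing zero regions are
#'   redrawn, so every donor has at least one region.
#' @param age_confound Mean age-at-death offset in years applied to the
#'   AA-NL group (default -4, emulating the demographic imbalance such
#'   cohorts show; set 0 for matched groups).
#' @param seed Integer seed; output is deterministic given all arguments.
#'
#' @return A tibble with one row per donor: `donor_id`, `group`,
#'   `age_at_death`, `sex`, `pmi`, `education`, the phenotype columns, and a
#'   `regions` list-column. The latent severity draw is kept in attribute
#'   `"truth"` for parameter-recovery testing.
#' @export
#' @examples
#' cohort <- generate_cohort(n_per_group = 10, region_coverage = 1, seed = 7)
#' nrow(cohort)
generate_cohort <- function(n_per_group, region_coverage = 0.75,
                            age_confound = -4, seed = 1) {
  if (!is.numeric(n_per_group) || length(n_per_group) != 1L ||
      is.na(n_per_group) || n_per_group < 2) {
    abort("`n_per_group` must be a single integer >= 2.")
  }
  if (!is.numeric(region_coverage) || region_coverage <= 0 ||
      region_coverage > 1) {
    abort("`region_coverage` must be in (0, 1].")
  }
  n_per_group <- as.integer(n_per_group)
  n <- 3L * n_per_group

  with_seed(seed, {
    group <- factor(rep(POP_GROUPS, each = n_per_group), levels = POP_GROUPS)
    donor_id <- sprintf("D%03d", seq_len(n))

    age_mu <- 86 + ifelse(group == "AA-NL", age_confound, 0)
    age_at_death <- pmin(110, pmax(60, rnorm(n, age_mu, 5.5)))
    sex <- factor(ifelse(runif(n) < 0.6, "F", "M"), levels = c("F", "M"))
    pmi <- pmin(72, rgamma(n, shape = 4, rate = 0.5))
    education <- pmax(0, rnorm(n, 14, 3))

    # shared latent severity drives all AD phenotypes
    z <- rnorm(n)
    braak <- findInterval(z + rnorm(n, 0, 0.6),
                          c(-1.5, -0.8, -0.2, 0.3, 0.8, 1.4))
    cerad_raw <- findInterval(z + rnorm(n, 0, 0.6), c(-0.5, 0.2, 0.9))
    cerad <- 4L - cerad_raw # high severity -> 1 (Definite AD)
    dx_lat <- z + rnorm(n, 0, 0.5)
    clinical_dx <- factor(
      ifelse(dx_lat < 0, "NCI", ifelse(dx_lat < 0.8, "MCI", "AD")),
      levels = c("NCI", "MCI", "AD")
    )
    neuritic_plaques <- pmax(0, 0.8 + 0.5 * z + rnorm(n, 0, 0.3))
    diffuse_plaques <- pmax(0, 0.9 + 0.45 * z + rnorm(n, 0, 0.35))
    amyloid_sqrt <- pmax(0, 1.2 + 0.6 * z + rnorm(n, 0, 0.4))
    tangles_sqrt <- pmax(0, 1.4 + 0.7 * z + rnorm(n, 0, 0.45))
    cog_decline <- 0.6 * z + rnorm(n, 0, 0.5)

    regions <- lapply(seq_len(n), function(i) {
      repeat {
        keep <- runif(3) < region_coverage
        if (any(keep)) return(BRAIN_REGIONS[keep])
      }
    })

    out <- tibble(
      donor_id = donor_id, group = group,
      age_at_death = age_at_death, sex = sex, pmi = pmi,
      education = education,
      cerad = as.integer(cerad), braak = as.integer(braak),
      neuritic_plaques = neuritic_plaques, diffuse_plaques = diffuse_plaques,
      amyloid_sqrt = amyloid_sqrt, tangles_sqrt = tangles_sqrt,
      clinical_dx = clinical_dx, cog_decline = cog_decline,
      regions = regions
    )
    attr(out, "truth") <- tibble(donor_id = donor_id, severity = z)
    out
  })
}

#' Expand a cohort into (donor, region) samples
#'
#' @param cohort A tibble from [generate_cohort()].
#' @return A tibble with one row per profiled (donor, region) sample,
#'   carrying all donor columns.
#' @export
cohort_samples <- function(cohort) {
  out <- tidyr::unnest(dplyr::mutate(cohort, region = regions),
                       cols = "region")
  out$regions <- NULL
  out$sample_id <- paste(out$donor_id, out$region, sep = "_")
  dplyr::relocate(out, sample_id, donor_id, region)
}

#' Apply the study's phenotype transforms to raw pathology measures
#'
#' Converts raw quantitative neuropathology and cognition measures to the
#' analysis scale used throughout the package: amyloid load and tangle
#' density are square-root transformed; regional plaque counts are scaled by
#' their per-region standard deviation (computed across donors) and averaged
#' over regions; and the person-specific slope of cognitive decline is
#' negated so that larger values mean steeper decline.
#'
#' @param raw A data frame with one row per donor containing numeric columns
#'   `amyloid` (percent area, >= 0), `tangles` (density, >= 0), `cog_slope`
#'   (mixed-model slope of global cognition; negative = decline), and one or
#'   more regional plaque-count columns named in `plaque_cols`.
#' @param plaque_cols Character vector naming the regional plaque-count
#'   columns to scale and average (default: all columns starting with
#'   `"plaq_"`).
#' @param plaque_sd Optional named numeric vector of per-region standard
#'   deviations (names matching `plaque_cols`), e.g. reference SDs from the
#'   full cohort. When `NULL` (default) each region's SD is computed across
#'   the donors in `raw`.
#' @return A tibble with columns `amyloid_sqrt`, `tangles_sqrt`,
#'   `plaques_scaled`, `cog_decline` (plus any identifier columns in `raw`).
#' @export
#' @examples
#' raw <- tibble::tibble(amyloid = c(4, 1), tangles = c(9, 0),
#'                       cog_slope = c(-0.05, 0.01),
#'                       plaq_a = c(1, 3), plaq_b = c(2, 6))
#' transform_phenotypes(raw)
transform_phenotypes <- function(raw,
                                 plaque_cols = grep("^plaq_", names(raw),
                                                    value = TRUE),
                                 plaque_sd = NULL) {
  raw <- as_tibble(raw)
  for (v in c("amyloid", "tangles", "cog_slope")) {
    if (!v %in% names(raw)) abort(sprintf("`raw` must contain column `%s`.", v))
  }
  if (any(raw$amyloid < 0, na.rm = TRUE) || any(raw$tangles < 0, na.rm = TRUE)) {
    abort("Raw amyloid and tangle values must be nonnegative.")
  }
  id_cols <- setdiff(names(raw),
                     c("amyloid", "tangles", "cog_slope", plaque_cols))
  out <- raw[id_cols]
  out$amyloid_sqrt <- sqrt(raw$amyloid)
  out$tangles_sqrt <- sqrt(raw$tangles)
  if (length(plaque_cols)) {
    scaled <- vapply(plaque_cols, function(v) {
      s <- if (!is.null(plaque_sd)) {
        plaque_sd[[v]]
      } else {
        sd(raw[[v]], na.rm = TRUE)
      }
      if (is.na(s) || s == 0) s <- 1 # constant region carries no spread
      raw[[v]] / s
    }, numeric(nrow(raw)))
    scaled <- matrix(scaled, nrow = nrow(raw))
    out$plaques_scaled <- rowMeans(scaled, na.rm = TRUE)
  }
  out$cog_decline <- -raw$cog_slope
  as_tibble(out)
}
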