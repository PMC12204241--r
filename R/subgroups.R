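#' Assemble donor feature vectors for molecular subgrouping
#'
#' Concatenates within-class normalized subcluster proportions (one block
#' per broad class) with per-donor median factor scores. Proportion blocks
#' are left on the simplex; factor-score columns are z-scaled by default so
#' high-variance factors do not dominate the correlation distance. Donors
#' missing any block are dropped (with a message).
#'
#' @param proportion_blocks Named list of proportion tibbles (each with
#'   `donor_id` and numeric proportion columns; e.g. region-filtered output
#'   of [normalize_proportions()] aggregated per donor).
#' @param factor_scores Optional tibble with `donor_id` and factor-score
#'   columns.
#' @param scale_factors z-scale the factor block (default `TRUE`).
#' @return Tibble: `donor_id` + feature columns.
#' @export
assemble_donor_features <- function(proportion_blocks, factor_scores = NULL,
                                    scale_factors = TRUE) {
  blocks <- purrr::imap(proportion_blocks, function(b, nm) {
    b <- as_tibble(b)
    num <- setdiff(names(b)[vapply(b, is.numeric, logical(1))],
                   c("total"))
    out <- b[c("donor_id", num)]
    names(out)[-1] <- paste(nm, num, sep = ".")
    out
  })
  joined <- purrr::reduce(blocks, function(a, b) {
    dplyr::inner_join(a, b, by = "donor_id")
  })
  if (!is.null(factor_scores)) {
    fs <- as_tibble(factor_scores)
    num <- setdiff(names(fs)[vapply(fs, is.numeric, logical(1))],
                   c("n_cells"))
    fs <- fs[c("donor_id", num)]
    before <- nrow(joined)
    joined <- dplyr::inner_join(joined, fs, by = "donor_id")
    if (nrow(joined) < before) {
      inform(sprintf("Dropped %d donor(s) lacking factor scores.",
                     before - nrow(joined)))
    }
    if (scale_factors) {
      # scale over the assembled donors so each factor has unit spread
      joined[num] <- lapply(joined[num], function(v) {
        s <- sd(v)
        if (is.na(s) || s == 0) v - mean(v) else (v - mean(v)) / s
      })
    }
  }
  joined
}

#' Cluster donors on correlation distance with Ward linkage
#'
#' Computes pairwise dissimilarities `1 - Pearson r` between donor feature
#' vectors, builds an agglomerative Ward tree (Lance-Williams update
#' applied directly to the correlation distances), cuts it at every k in
#' `k_range`, scores each cut by the median silhouette width under the same
#' distance, and picks the k with the largest median silhouette (smallest k
#' on ties). Donors with constant feature vectors (undefined correlation)
#' are dropped with a warning.
#'
#' @param features Tibble: `donor_id` + numeric feature columns (>= 3
#'   donors).
#' @param k_range Candidate numbers of subgroups (default `2:8`, truncated
#'   to `n - 1`).
#' @return Object of class `donor_clustering`: `tree` (hclust), `labels`
#'   (tibble `donor_id`, `k`, `cluster`), `silhouette` (tibble `k`,
#'   `median_silhouette`), `chosen_k`, `dist`.
#' @export
cluster_donors <- function(features, k_range = 2:8) {
  features <- as_tibble(features)
  num <- names(features)[vapply(features, is.numeric, logical(1))]
  X <- as.matrix(features[num])
  rownames(X) <- features$donor_id
  const <- apply(X, 1, sd) == 0
  if (any(const)) {
    warn(sprintf("Dropping %d donor(s) with constant features.", sum(const)))
    X <- X[!const, , drop = FALSE]
  }
  n <- nrow(X)
  if (n < 3) abort("Need at least 3 donors with usable features.")
  k_range <- sort(unique(pmin(k_range, n - 1L)))
  k_range <- k_range[k_range >= 2]

  d <- as.dist(1 - cor(t(X)))
  tree <- hclust(d, method = "ward.D")
  dm <- as.matrix(d)
  sil <- purrr::map_dfr(k_range, function(kk) {
    labs <- cutree(tree, k = kk)
    sw <- cluster::silhouette(labs, dmatrix = dm)
    tibble(k = kk, median_silhouette = median(sw[, "sil_width"]))
  })
  chosen <- sil$k[which.max(sil$median_silhouette)] # which.max -> smallest tie
  labels <- purrr::map_dfr(k_range, function(kk) {
    labs <- unname(cutree(tree, k = kk))
    tibble(donor_id = rownames(X), k = kk, cluster = labs)
  })
  structure(list(tree = tree, labels = labels, silhouette = sil,
                 chosen_k = chosen, dist = d),
            class = "donor_clustering")
}

#' @export
print.donor_clustering <- function(x, ...) {
  cat("Donor clustering (1 - Pearson r, Ward):",
      attr(x$dist, "Size"), "donors; chosen k =", x$chosen_k, "\n")
  invisible(x)
}

#' @rdname tidy
#' @export
tidy.donor_clustering <- function(x, ...) {
  dplyr::filter(x$labels, k == x$chosen_k)
}

#' @rdname tidy
#' @export
glance.donor_clustering <- function(x, ...) {
  tibble(chosen_k = x$chosen_k,
         median_silhouette =
           x$silhouette$median_silhouette[x$silhouette$k == x$chosen_k],
         n_donors = attr(x$dist, "Size"))
}

#' Summarize subgroup composition
#'
#' Contingency fractions of clinical diagnosis, Braak bands (0-2, 3-4,
#' 5-6), CERAD score and population group within each donor subgroup.
#'
#' @param labels Tibble with `donor_id` and `cluster` (e.g.
#'   `tidy(cluster_donors(...))`).
#' @param cohort Donor table.
#' @param vars Annotation columns to tabulate.
#' @return Tibble: `cluster`, `variable`, `level`, `n`, `fraction`
#'   (fractions sum to 1 within cluster x variable).
#' @export
summarize_groups <- function(labels, cohort,
                             vars = c("clinical_dx", "braak_band", "cerad",
                                      "group")) {
  df <- dplyr::inner_join(as_tibble(labels), as_tibble(cohort),
                          by = "donor_id")
  if ("braak" %in% names(df)) {
    df$braak_band <- cut(df$braak, c(-1, 2, 4, 6),
                         labels = c("0-2", "3-4", "5-6"))
  }
  vars <- intersect(vars, names(df))
  purrr::map_dfr(vars, function(v) {
    tb <- dplyr::count(df, cluster, level = as.character(.data[[v]]))
    tb <- dplyr::mutate(dplyr::group_by(tb, cluster),
                        fraction = n / sum(n))
    dplyr::mutate(dplyr::ungroup(tb), variable = v, .before = "level")
  })
}

#' Hypergeometric enrichment of annotations in subgroups
#'
#' For every (subgroup, annotation level) pair, tests over-representation
#' with the upper-tail hypergeometric probability `P(X >= x)` (population
#' size = universe, successes = donors with the level, draws = subgroup
#' size), then applies Benjamini-Hochberg across all pairs.
#'
#' @param labels Tibble with `donor_id`, `cluster`.
#' @param cohort Donor table (the universe is the set of labeled donors).
#' @param var Annotation column to test (e.g. `"group"`).
#' @return Tibble: `cluster`, `level`, `x` (observed), `k_universe`,
#'   `n_group`, `n_universe`, `p_value`, `p_adj`.
#' @export
enrichment_test <- function(labels, cohort, var = "group") {
  df <- dplyr::inner_join(as_tibble(labels), as_tibble(cohort),
                          by = "donor_id")
  if (!nrow(df)) abort("Empty group: no labeled donors found in cohort.")
  N <- nrow(df)
  lv <- unique(as.character(df[[var]]))
  out <- purrr::map_dfr(sort(unique(df$cluster)), function(g) {
    members <- df[df$cluster == g, ]
    if (!nrow(members)) abort("Empty group.")
    purrr::map_dfr(sort(lv), function(l) {
      x <- sum(as.character(members[[var]]) == l)
      K <- sum(as.character(df[[var]]) == l)
      n <- nrow(members)
      tibble(
        cluster = g, level = l, x = x, k_universe = K,
        n_group = n, n_universe = N,
        p_value = phyper(x - 1, K, N - K, n, lower.tail = FALSE)
      )
    })
  })
  out$p_adj <- p.adjust(out$p_value, method = "BH")
  out
}
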