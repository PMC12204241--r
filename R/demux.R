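#' Validate a pooled-library design
#'
#' A pooling plan is valid when every library contains exactly 3 distinct
#' donors (a structural requirement; violations raise an error) and no
#' unordered pair of donors co-occurs in more than one library (the design
#' constraint that makes genotype-free identity assignment possible;
#' violations are reported, not raised).
#'
#' @param plan Tibble with columns `library`, `donor_id` (and optionally
#'   `region`).
#' @return List: `valid` (logical), `violations` (tibble `donor1`,
#'   `donor2`, `libraries`).
#' @export
#' @examples
#' plan <- make_pool_plan(9)
#' validate_design(plan)$valid
validate_design <- function(plan) {
  plan <- as_tibble(plan)
  sizes <- table(plan$library)
  dup <- tapply(plan$donor_id, plan$library,
                function(d) anyDuplicated(d) > 0)
  if (any(sizes != 3) || any(dup)) {
    abort("Structural error: every library must have exactly 3 distinct donors.")
  }
  pair_rows <- purrr::map_dfr(split(plan$donor_id, plan$library),
                              function(d) {
    cmb <- utils::combn(sort(d), 2)
    tibble(donor1 = cmb[1, ], donor2 = cmb[2, ])
  }, .id = "library")
  viol <- dplyr::filter(
    dplyr::summarise(dplyr::group_by(pair_rows, donor1, donor2),
                     n_libs = dplyr::n(),
                     libraries = paste(sort(library), collapse = ","),
                     .groups = "drop"),
    n_libs > 1
  )
  list(valid = nrow(viol) == 0, violations = viol)
}

utils::globalVariables(c("n_libs", "libraries"))

#' Genotype-signature concordance
#'
#' Fraction of SNPs, non-missing in both signatures, at which the
#' variant-allele fractions match exactly.
#'
#' @param sig1,sig2 Numeric VAF vectors on a shared SNP panel (values in
#'   {0, 0.5, 1} or `NA` for missing).
#' @return Fraction in \[0, 1\].
#' @export
#' @examples
#' concordance(c(0, 0.5, 1), c(0, 0.5, 0))
concordance <- function(sig1, sig2) {
  if (length(sig1) != length(sig2)) {
    abort("Signatures must be on the same SNP panel.")
  }
  both <- !is.na(sig1) & !is.na(sig2)
  if (!any(both)) abort("No SNPs defined in both signatures.")
  mean(sig1[both] == sig2[both])
}

#' Assign anonymous genotype clusters to donors
#'
#' Links cluster pairs from different libraries whose signatures agree at a
#' concordance of at least `min_concordance` over at least
#' `min_shared_snps` shared SNPs, takes connected components of the
#' resulting graph as putative donors, and matches each component's set of
#' libraries (its fingerprint) against the plan: a component is assigned a
#' donor only when exactly one donor's planned library set equals the
#' fingerprint. Components matching no donor uniquely are left unassigned;
#' a component whose fingerprint matches several donors (possible only if
#' two donors share an identical library set, e.g. genetically identical
#' donors collapsing into one component) raises an ambiguity error listing
#' the candidates.
#'
#' @param vaf Signature matrix, one row per (library, cluster), as produced
#'   by [generate_pooled_genotypes()] (rownames `"<library>.<cluster>"`).
#' @param clusters Tibble with `library`, `cluster` in row order of `vaf`.
#' @param plan Pooling plan; must pass [validate_design()].
#' @param min_concordance Edge threshold (default 0.9).
#' @param min_shared_snps Minimum SNPs shared by an edge (default 100).
#' @return Tibble: `library`, `cluster`, `component`, `donor_id` (`NA` when
#'   unassigned).
#' @export
assign_identities <- function(vaf, clusters, plan, min_concordance = 0.9,
                              min_shared_snps = 100) {
  chk <- validate_design(plan)
  if (!chk$valid) {
    abort("`plan` violates the no-repeated-pair design constraint.")
  }
  clusters <- as_tibble(clusters)
  n <- nrow(vaf)
  stopifnot(nrow(clusters) == n)

  edges <- list()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (clusters$library[i] == clusters$library[j]) next
      both <- !is.na(vaf[i, ]) & !is.na(vaf[j, ])
      if (sum(both) < min_shared_snps) next
      conc <- mean(vaf[i, both] == vaf[j, both])
      if (conc >= min_concordance) {
        edges[[length(edges) + 1L]] <- c(i, j)
      }
    }
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (length(edges)) {
    g <- igraph::add_edges(g, unlist(edges))
  }
  comp <- igraph::components(g)$membership

  donor_sets <- tapply(plan$library, plan$donor_id,
                       function(l) paste(sort(unique(l)), collapse = ","))
  assignment <- rep(NA_character_, n)
  for (cmp in unique(comp)) {
    idx <- which(comp == cmp)
    fp <- paste(sort(unique(clusters$library[idx])), collapse = ",")
    matches <- names(donor_sets)[donor_sets == fp]
    if (length(matches) == 1) {
      assignment[idx] <- matches
    } else if (length(matches) > 1) {
      abort(sprintf(
        "Ambiguous fingerprint {%s}: candidate donors %s share a library set.",
        fp, paste(matches, collapse = ", ")))
    }
  }
  tibble(
    library = clusters$library, cluster = clusters$cluster,
    component = as.integer(comp), donor_id = assignment
  )
}
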