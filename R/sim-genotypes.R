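#' Build a no-repeated-pair pooling plan on a donor grid
#'
#' Convenience constructor for a valid pooled-library design: donors are
#' laid out on a 3-by-m grid and libraries are the rows and columns, so
#' every library holds exactly 3 donors and no pair of donors co-occurs in
#' more than one library (a resolvable-design argument: two libraries share
#' at most one grid point).
#'
#' @param n_donors Number of donors; must be a multiple of 3 with
#'   `n_donors/3 >= 3` so column libraries also have 3 members (9 donors
#'   give the classic 3x3 grid with 6 libraries).
#' @param regions Regions cycled over library memberships (cosmetic; the
#'   design constraint concerns donors only).
#' @return A tibble with columns `library`, `donor_id`, `region` (three rows
#'   per library).
#' @export
#' @examples
#' make_pool_plan(9)
make_pool_plan <- function(n_donors, regions = BRAIN_REGIONS) {
  if (n_donors %% 3 != 0 || n_donors < 9) {
    abort("`n_donors` must be a multiple of 3, at least 9.")
  }
  m <- n_donors / 3
  grid <- matrix(sprintf("D%03d", seq_len(n_donors)), nrow = 3)
  libs <- c(
    lapply(seq_len(3), function(r) grid[r, seq_len(3)]), # rows (first 3 cols)
    lapply(seq_len(3), function(c) grid[, c])            # columns
  )
  if (m > 3) {
    libs <- c(libs, lapply(4:m, function(c) grid[, c]))
  }
  purrr::imap_dfr(libs, function(members, i) {
    tibble(
      library = sprintf("L%02d", i),
      donor_id = members,
      region = rep_len(regions, 3L)
    )
  })
}

# deterministic miscall map on VAF values {0, 0.5, 1}: two independently
# corrupted copies of the same genotype agree iff both are correct or both
# miscalled, giving per-SNP concordance (1-e)^2 + e^2.
miscall_vaf <- function(v) {
  out <- v
  out[v == 0] <- 1
  out[v == 0.5] <- 1
  out[v == 1] <- 0
  out
}

#' Simulate pooled-library genotype signatures
#'
#' Each donor receives one latent diploid genotype per SNP (allele
#' frequencies uniform on \[0.05, 0.5\], Hardy-Weinberg genotype draws coded
#' as variant-allele fractions 0/0.5/1). Every library in the plan yields
#' three anonymous VAF vectors (one per pooled donor, cluster order
#' shuffled), each corrupted independently per SNP with probability
#' `error_rate` by a deterministic miscall map, so two signatures of the
#' same donor agree at a SNP with probability `(1-e)^2 + e^2`.
#'
#' Plans violating the no-repeated-pair constraint are still generable (so
#' the validator can be exercised); the violation is flagged in the result.
#'
#' @param plan Pooling plan tibble (`library`, `donor_id`, `region`), e.g.
#'   from [make_pool_plan()]. Every library must contain exactly 3 distinct
#'   donors.
#' @param n_snps Size of the shared SNP panel.
#' @param error_rate Per-SNP miscall probability, in \[0, 0.5).
#' @param seed Integer seed.
#' @return A list: `vaf` (matrix, one row per (library, cluster) signature,
#'   rownames `"<library>.<cluster>"`), `clusters` (tibble `library`,
#'   `cluster`), `truth` (tibble `library`, `cluster`, `donor_id`),
#'   `genotypes` (donor x SNP latent VAF matrix), `plan`, and
#'   `design_valid` (logical flag from [validate_design()]).
#' @export
generate_pooled_genotypes <- function(plan, n_snps = 500, error_rate = 0.01,
                                      seed = 1) {
  if (!is.numeric(error_rate) || error_rate < 0 || error_rate >= 0.5) {
    abort("`error_rate` must be in [0, 0.5).")
  }
  sizes <- table(plan$library)
  dup <- tapply(plan$donor_id, plan$library, function(d) anyDuplicated(d) > 0)
  if (any(sizes != 3) || any(dup)) {
    abort("Every library in `plan` must contain exactly 3 distinct donors.")
  }
  donors <- sort(unique(plan$donor_id))
  libs <- unique(plan$library)

  with_seed(seed, {
    maf <- runif(n_snps, 0.05, 0.5)
    geno <- t(vapply(seq_along(donors), function(i) {
      rbinom(n_snps, 2, maf) / 2
    }, numeric(n_snps)))
    dimnames(geno) <- list(donors, sprintf("snp%04d", seq_len(n_snps)))

    rows <- list(); truth <- list()
    for (lib in libs) {
      members <- plan$donor_id[plan$library == lib]
      ord <- sample(3L) # anonymize cluster order
      for (k in seq_len(3L)) {
        d <- members[ord[k]]
        v <- geno[d, ]
        if (error_rate > 0) {
          flip <- runif(n_snps) < error_rate
          v[flip] <- miscall_vaf(v[flip])
        }
        rows[[paste(lib, k - 1L, sep = ".")]] <- v
        truth[[length(truth) + 1L]] <-
          tibble(library = lib, cluster = k - 1L, donor_id = d)
      }
    }
    vaf <- do.call(rbind, rows)
    truth <- dplyr::bind_rows(truth)
    list(
      vaf = vaf,
      clusters = truth[c("library", "cluster")],
      truth = truth,
      genotypes = geno,
      plan = plan,
      design_valid = validate_design(plan)$valid
    )
  })
}
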