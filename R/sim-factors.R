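#' Simulate factor-structured count matrices
#'
#' Emulates the generative structure of a hierarchical Poisson
#' factorization: counts are Poisson with rate equal to the product of a
#' nonnegative cells-by-K score matrix and a K-by-genes weight matrix. Used
#' as ground truth for the factorization engine and the factor-number
#' selection rule.
#'
#' @param n_cells,n_genes Matrix dimensions.
#' @param k_true Number of latent programs (>= 1).
#' @param duplicate_last If `TRUE`, the gene-weight vector of the last
#'   program is an exact copy of the previous one, planting a duplicated
#'   program (the resulting rate matrix has rank `k_true - 1`). Requires
#'   `k_true >= 2`.
#' @param mean_depth Approximate mean total count per cell (default 2000).
#' @param seed Integer seed.
#' @return A list: `counts` (cells x genes integer matrix), `cell_scores`
#'   (cells x k_true), `gene_weights` (genes x k_true), `k_true`.
#' @export
generate_factor_counts <- function(n_cells, n_genes, k_true,
                                   duplicate_last = FALSE,
                                   mean_depth = 2000, seed = 1) {
  if (!is.numeric(k_true) || k_true < 1) abort("`k_true` must be >= 1.")
  if (duplicate_last && k_true < 2) {
    abort("`duplicate_last` requires `k_true` >= 2.")
  }
  k_true <- as.integer(k_true)
  with_seed(seed, {
    theta <- matrix(rgamma(n_cells * k_true, shape = 0.7, rate = 1),
                    n_cells, k_true)
    w <- matrix(rgamma(n_genes * k_true, shape = 0.3, rate = 1),
                n_genes, k_true)
    if (duplicate_last) w[, k_true] <- w[, k_true - 1L]
    w <- sweep(w, 2, colSums(w), "/") # gene weights on a simplex per program
    rate <- theta %*% t(w)
    scale <- mean_depth / mean(rowSums(rate))
    theta <- theta * scale
    rate <- rate * scale
    counts <- matrix(stats::rpois(length(rate), rate), n_cells, n_genes)
    dimnames(counts) <- list(sprintf("cell%04d", seq_len(n_cells)),
                             sprintf("g%04d", seq_len(n_genes)))
    # keep every cell usable downstream (factorizers reject all-zero rows)
    empty <- rowSums(counts) == 0
    if (any(empty)) counts[empty, 1L] <- 1L
    list(counts = counts, cell_scores = theta, gene_weights = w,
         k_true = k_true)
  })
}
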