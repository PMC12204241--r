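#' Factorize a count matrix into nonnegative expression programs
#'
#' Pluggable engine standing in for a probabilistic count factorization:
#' the default is multiplicative-update NMF minimizing the generalized
#' Kullback-Leibler divergence (the objective whose maximum-likelihood
#' counterpart is the Poisson factorization), run from a seeded random
#' initialization. The objective is non-increasing across iterations (a
#' property of the multiplicative updates) and the run is deterministic
#' given the seed. Gene-weight columns are renormalized to sum to 1, with
#' the scale moved into the cell scores, so downstream correlation and
#' top-gene rules are reproducible across runs.
#'
#' @param counts Cells x genes nonnegative matrix (dense or `dgCMatrix`);
#'   no all-zero rows.
#' @param K Number of programs (1 <= K <= min(dim)).
#' @param seed Integer seed for the initialization.
#' @param engine `"klnmf"` (default) or a function
#'   `function(counts, K, seed)` returning a list with `gene_weights`
#'   (genes x K) and `cell_scores` (cells x K) — e.g. matrices exported
#'   from an external hierarchical Poisson factorization run.
#' @param n_iter Maximum multiplicative-update iterations (default 500).
#' @param tol Relative objective-change tolerance (default 1e-6).
#' @return Object of class `factor_model`: `gene_weights` (genes x K,
#'   columns sum to 1), `cell_scores` (cells x K), `K`, `engine`,
#'   `objective` (per-iteration trace for the default engine), `converged`.
#' @export
factorize <- function(counts, K, seed = 1, engine = "klnmf",
                      n_iter = 500, tol = 1e-6) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) abort("`counts` must be nonnegative.")
  if (any(rowSums(counts) == 0)) abort("`counts` has all-zero rows.")
  if (!is.numeric(K) || K < 1 || K > min(dim(counts))) {
    abort("`K` must satisfy 1 <= K <= min(dim(counts)).")
  }
  K <- as.integer(K)

  if (is.function(engine)) {
    raw <- engine(counts, K, seed)
    model <- list(gene_weights = raw$gene_weights,
                  cell_scores = raw$cell_scores,
                  objective = raw$objective %||% numeric(0),
                  converged = raw$converged %||% TRUE)
    label <- "custom"
  } else if (identical(engine, "klnmf")) {
    model <- klnmf(counts, K, seed, n_iter, tol)
    label <- "klnmf"
  } else {
    abort("`engine` must be \"klnmf\" or a function.")
  }
  gw <- model$gene_weights
  cs <- model$cell_scores
  if (any(gw < 0) || any(cs < 0)) abort("Engine returned negative entries.")
  # column renormalization: gene-weight columns on the simplex
  csum <- colSums(gw)
  csum[csum == 0] <- 1
  gw <- sweep(gw, 2, csum, "/")
  cs <- sweep(cs, 2, csum, "*")
  colnames(gw) <- colnames(cs) <- sprintf("F%02d", seq_len(K))
  rownames(gw) <- colnames(counts)
  rownames(cs) <- rownames(counts)
  structure(list(gene_weights = gw, cell_scores = cs, K = K,
                 engine = label, objective = model$objective,
                 converged = model$converged),
            class = "factor_model")
}

# Multiplicative-update NMF under generalized KL divergence.
# V ~ W H with W: cells x K (scores), H: K x genes (weights).
klnmf <- function(V, K, seed, n_iter, tol) {
  n <- nrow(V); m <- ncol(V)
  obj <- function(Vhat) {
    pos <- V > 0
    sum(V[pos] * log(V[pos] / Vhat[pos])) - sum(V) + sum(Vhat)
  }
  with_seed(seed, {
    W <- matrix(runif(n * K, 0.5, 1.5), n, K) * sqrt(mean(V) / K)
    H <- matrix(runif(K * m, 0.5, 1.5), K, m) * sqrt(mean(V) / K)
    eps <- 1e-10
    Vhat <- W %*% H
    trace <- obj(Vhat)
    converged <- FALSE
    for (it in seq_len(n_iter)) {
      R <- V / pmax(Vhat, eps)
      W <- W * (R %*% t(H)) / pmax(matrix(rowSums(H), n, K, byrow = TRUE), eps)
      Vhat <- W %*% H
      R <- V / pmax(Vhat, eps)
      H <- H * (t(W) %*% R) / pmax(matrix(colSums(W), K, m), eps)
      Vhat <- W %*% H
      o <- obj(Vhat)
      trace <- c(trace, o)
      rel <- abs(trace[it] - o) / (abs(trace[it]) + eps)
      if (rel < tol) { converged <- TRUE; break }
    }
    list(gene_weights = t(H), cell_scores = W, objective = trace,
         converged = converged)
  })
}

#' @export
print.factor_model <- function(x, ...) {
  cat(sprintf("Factor model (%s): %d cells x %d genes, K = %d\n",
              x$engine, nrow(x$cell_scores), nrow(x$gene_weights), x$K))
  invisible(x)
}

#' @rdname tidy
#' @export
tidy.factor_model <- function(x, ...) {
  gw <- as_tibble(x$gene_weights)
  gw$gene <- rownames(x$gene_weights)
  tidyr::pivot_longer(gw, -gene, names_to = "factor_id",
                      values_to = "weight")
}

# Max pairwise Pearson correlation among columns; 0 when fewer than 2
# columns or when degenerate (constant) columns make r undefined.
max_pairwise_cor <- function(M) {
  if (ncol(M) < 2) return(0)
  sds <- apply(M, 2, sd)
  M <- M[, sds > 0, drop = FALSE]
  if (ncol(M) < 2) return(0)
  cm <- cor(M)
  max(cm[upper.tri(cm)])
}

#' Apply the factor-number rule to a correlation table
#'
#' Given per-K maximum pairwise factor correlations, returns the largest K
#' whose maximum does not exceed `corr_max` (the rule is "largest factor
#' set", an argmax over the candidate grid, not the first crossing; set
#' `first_crossing = TRUE` for the alternative reading that stops at the
#' first K violating the rule). When no K qualifies, the smallest K in the
#' grid is returned with `warning_flag = TRUE`.
#'
#' @param corr_table Tibble with columns `K` and `max_corr`.
#' @param corr_max Correlation ceiling (default 0.75).
#' @param first_crossing Use the first-crossing reading (default `FALSE`).
#' @return List: `K` (chosen), `warning_flag`.
#' @export
choose_k_from_corr <- function(corr_table, corr_max = 0.75,
                               first_crossing = FALSE) {
  tb <- dplyr::arrange(as_tibble(corr_table), K)
  ok <- tb$max_corr <= corr_max
  if (!any(ok)) {
    return(list(K = min(tb$K), warning_flag = TRUE))
  }
  if (first_crossing) {
    bad <- which(!ok)
    last <- if (length(bad)) min(bad) - 1L else nrow(tb)
    if (last < 1L) return(list(K = min(tb$K), warning_flag = TRUE))
    return(list(K = tb$K[last], warning_flag = FALSE))
  }
  list(K = max(tb$K[ok]), warning_flag = FALSE)
}

#' Select the number of factors by the pairwise-correlation rule
#'
#' Fits a model at every K in the grid and computes the maximum pairwise
#' Pearson correlation among gene-weight columns and among cell-score
#' columns; the chosen K is the largest whose maximum (over both matrices)
#' is at most `corr_max`. K = 1 has no pairs and trivially satisfies the
#' rule. Correlations are compared within each K's own model.
#'
#' @inheritParams factorize
#' @param k_grid Candidate K values (ascending).
#' @param corr_max Correlation ceiling (default 0.75).
#' @param first_crossing See [choose_k_from_corr()].
#' @return List of class `factor_selection`: `K` (chosen),
#'   `warning_flag`, `corr_table` (tibble `K`, `max_gene_corr`,
#'   `max_cell_corr`, `max_corr`), `models` (per-K `factor_model`s).
#' @export
select_num_factors <- function(counts, k_grid, corr_max = 0.75, seed = 1,
                               engine = "klnmf", first_crossing = FALSE,
                               ...) {
  if (!length(k_grid)) abort("`k_grid` must be nonempty.")
  k_grid <- sort(unique(as.integer(k_grid)))
  models <- lapply(k_grid, function(k) {
    factorize(counts, k, seed = seed, engine = engine, ...)
  })
  corr_table <- purrr::map2_dfr(models, k_grid, function(m, k) {
    gc <- max_pairwise_cor(m$gene_weights)
    cc <- max_pairwise_cor(m$cell_scores)
    tibble(K = k, max_gene_corr = gc, max_cell_corr = cc,
           max_corr = max(gc, cc))
  })
  sel <- choose_k_from_corr(corr_table, corr_max, first_crossing)
  structure(list(K = sel$K, warning_flag = sel$warning_flag,
                 corr_table = corr_table,
                 models = setNames(models, paste0("K", k_grid))),
            class = "factor_selection")
}

#' @export
print.factor_selection <- function(x, ...) {
  cat("Factor-number selection: chosen K =", x$K,
      if (x$warning_flag) "(no K satisfied the rule; smallest returned)",
      "\n")
  print(x$corr_table)
  invisible(x)
}

#' Report top genes per factor
#'
#' Genes with mean pseudobulk CPM strictly above `cpm_min` are ranked by
#' descending weight within each factor; the top `n_top` are reported, ties
#' broken lexicographically by gene name. Factors with fewer than `n_top`
#' eligible genes return all eligible genes and are flagged.
#'
#' @param model A `factor_model`.
#' @param pseudobulk_cpm Named numeric vector of mean CPM per gene, aligned
#'   to `rownames(model$gene_weights)`.
#' @param n_top Genes per factor (default 5).
#' @param cpm_min CPM floor, strict (default 10).
#' @return Tibble with `factor_id`, `gene`, `weight`, `rank`, `short_list`
#'   (TRUE when the factor had fewer than `n_top` eligible genes).
#' @export
top_genes <- function(model, pseudobulk_cpm, n_top = 5, cpm_min = 10) {
  gw <- model$gene_weights
  genes <- rownames(gw)
  if (is.null(names(pseudobulk_cpm))) {
    if (length(pseudobulk_cpm) != length(genes)) {
      abort("`pseudobulk_cpm` must align with the model's genes.")
    }
    names(pseudobulk_cpm) <- genes
  }
  cpm <- pseudobulk_cpm[genes]
  eligible <- !is.na(cpm) & cpm > cpm_min
  purrr::map_dfr(seq_len(ncol(gw)), function(j) {
    w <- gw[eligible, j]
    g <- genes[eligible]
    ord <- order(-w, g)
    take <- head(ord, n_top)
    tibble(
      factor_id = colnames(gw)[j],
      gene = g[take], weight = unname(w[take]),
      rank = seq_along(take),
      short_list = length(ord) < n_top
    )
  })
}

#' Median factor score per sample
#'
#' @param model A `factor_model`.
#' @param cell_samples Tibble mapping cells to samples: columns `cell`
#'   (matching `rownames(model$cell_scores)`) and `sample_id`.
#' @return Tibble: `sample_id`, one column per factor (the median cell
#'   score), and `n_cells`.
#' @export
median_factor_scores <- function(model, cell_samples) {
  cs <- model$cell_scores
  idx <- match(cell_samples$cell, rownames(cs))
  if (anyNA(idx)) abort("Every cell must map to a model row.")
  df <- dplyr::bind_cols(
    tibble(sample_id = cell_samples$sample_id),
    as_tibble(cs[idx, , drop = FALSE])
  )
  dplyr::summarise(
    dplyr::group_by(df, sample_id),
    dplyr::across(dplyr::everything(), median),
    n_cells = dplyr::n(),
    .groups = "drop"
  )
}

#' Associate per-sample median factor scores with phenotypes
#'
#' Computes the median factor score per (donor, region) sample and fits,
#' within each population group and region, an ordinary least-squares model
#' of the median on the trait plus the standard covariates (education added
#' for cognitive traits). The output matches [fit_group_associations()]
#' column-for-column (with `factor_id` in place of `subcluster`), so it
#' feeds [meta_analyze()] unchanged.
#'
#' @param model A `factor_model`.
#' @param cell_samples Cell-to-sample map (see [median_factor_scores()]);
#'   `sample_id` must be `"<donor_id>_<region>"` as produced by
#'   [cohort_samples()].
#' @param cohort Donor table.
#' @param traits Trait specification (default [default_trait_spec()]).
#' @param covariates Base covariates.
#' @return Tibble with one row per (group, region, factor, trait):
#'   `beta_hat`, `robust_se` (OLS SE), `p_value`, `n_samples`, `converged`.
#' @export
associate_factors <- function(model, cell_samples, cohort,
                              traits = default_trait_spec(),
                              covariates = c("age_at_death", "sex", "pmi")) {
  if (is.character(traits)) {
    traits <- tibble(trait = traits, source = traits, cognitive = FALSE)
  }
  med <- median_factor_scores(model, cell_samples)
  samples <- cohort_samples(cohort)
  data <- dplyr::inner_join(med, samples, by = "sample_id")
  data <- add_trait_contrasts(data)
  factors <- colnames(model$cell_scores)
  groups <- levels(factor(data$group))
  regions <- unique(data$region)

  grid <- tidyr::expand_grid(group = groups, region = regions,
                             trait_row = seq_len(nrow(traits)))
  purrr::pmap_dfr(grid, function(group, region, trait_row) {
    tr <- traits$trait[trait_row]
    cov <- c(covariates, if (traits$cognitive[trait_row]) "education")
    d <- data[data$group == group & data$region == region, , drop = FALSE]
    if (!nrow(d) || !tr %in% names(d)) return(NULL)
    d <- d[complete.cases(as.data.frame(d)[c(tr, cov)]), , drop = FALSE]
    n_terms <- 2L + length(cov)
    if (nrow(d) < n_terms + 1L) return(NULL)
    purrr::map_dfr(factors, function(f) {
      fml <- stats::reformulate(c(tr, cov), response = f)
      fit <- tryCatch(lm(fml, data = d), error = function(e) NULL)
      if (is.null(fit)) return(NULL)
      sm <- summary(fit)$coefficients
      row <- grep(paste0("^", tr), rownames(sm))[1]
      if (is.na(row)) return(NULL)
      tibble(
        group = group, region = region, factor_id = f, trait = tr,
        beta_hat = sm[row, 1], robust_se = sm[row, 2],
        t_stat = sm[row, 3], p_value = sm[row, 4],
        n_samples = nrow(d), converged = TRUE
      )
    })
  })
}
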