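#' Nucleus-level quality filter
#'
#' Retains nuclei with strictly more than `min_umis` UMIs and a
#' mitochondrial UMI percentage strictly below `max_mito_pct` (both
#' thresholds strict: a nucleus at exactly 500 UMIs or exactly 5% is
#' removed).
#'
#' @param nuclei Tibble with numeric columns `total_umis` and `mito_pct`
#'   (percent, 0-100).
#' @param min_umis UMI floor (default 500).
#' @param max_mito_pct Mitochondrial ceiling in percent (default 5).
#' @return The retained subset of `nuclei`.
#' @export
#' @examples
#' qc_filter(tibble::tibble(total_umis = c(500, 501), mito_pct = c(1, 5)))
qc_filter <- function(nuclei, min_umis = 500, max_mito_pct = 5) {
  dplyr::filter(as_tibble(nuclei),
                total_umis > min_umis, mito_pct < max_mito_pct)
}

# CPM per row with no pseudocount; pseudocount enters the log-ratio only.
row_cpm <- function(mat) {
  rs <- rowSums(mat)
  if (any(rs <= 0)) abort("Every profile needs a positive total count.")
  mat / rs * 1e6
}

# Directional separability of one subcluster pair on CPM + pseudocount 1.
pair_separability <- function(cpm_a, cpm_b, min_genes, lfc_min) {
  lfc <- log2((cpm_a + 1) / (cpm_b + 1))
  n_up <- sum(lfc > lfc_min)
  n_dn <- sum(lfc < -lfc_min)
  list(separable = n_up >= min_genes && n_dn >= min_genes,
       score = n_up + n_dn)
}

#' Merge transcriptomically indistinct subclusters
#'
#' Two subclusters are separable when their pseudobulk profiles show at
#' least `min_genes` genes with log2 fold change above `lfc_min` AND at
#' least `min_genes` genes below `-lfc_min` (both directions required; fold
#' changes are computed on CPM with a pseudocount of 1). While any pair
#' fails the rule, the least-separable failing pair (smallest total count of
#' qualifying genes, ties broken lexicographically by the sorted label pair)
#' is merged by summing counts, and separability is recomputed. Merged
#' labels are the "+"-joined sorted constituent labels, which makes the
#' procedure invariant to input order and idempotent.
#'
#' @param pseudobulk Numeric matrix of summed counts, one row per
#'   subcluster (rownames = labels), columns = genes.
#' @param min_genes Qualifying genes required per direction (default 4).
#' @param lfc_min Absolute log2-fold-change threshold (default 2).
#' @return List of class `merge_result`: `label_map` (tibble `old_label`,
#'   `new_label`), `pseudobulk` (merged count matrix), `merges` (tibble of
#'   merge steps).
#' @export
merge_subclusters <- function(pseudobulk, min_genes = 4, lfc_min = 2) {
  pseudobulk <- as.matrix(pseudobulk)
  if (nrow(pseudobulk) < 2) abort("Need at least 2 subclusters.")
  if (is.null(rownames(pseudobulk))) {
    rownames(pseudobulk) <- paste0("SC", seq_len(nrow(pseudobulk)))
  }
  originals <- rownames(pseudobulk)
  # members[[label]] = original labels merged into it
  members <- setNames(as.list(originals), originals)
  counts <- pseudobulk
  merges <- list()

  repeat {
    labs <- rownames(counts)
    if (length(labs) < 2) break
    cpm <- row_cpm(counts)
    worst <- NULL
    for (i in seq_len(length(labs) - 1)) {
      for (j in (i + 1):length(labs)) {
        sep <- pair_separability(cpm[i, ], cpm[j, ], min_genes, lfc_min)
        if (!sep$separable) {
          key <- sort(c(labs[i], labs[j]))
          cand <- list(i = i, j = j, score = sep$score, key = key)
          if (is.null(worst) || cand$score < worst$score ||
              (cand$score == worst$score &&
                 paste(cand$key, collapse = "\r") <
                 paste(worst$key, collapse = "\r"))) {
            worst <- cand
          }
        }
      }
    }
    if (is.null(worst)) break
    a <- labs[worst$i]; b <- labs[worst$j]
    new_members <- sort(c(members[[a]], members[[b]]))
    new_label <- paste(new_members, collapse = "+")
    merged_row <- counts[a, ] + counts[b, ]
    counts <- counts[!(rownames(counts) %in% c(a, b)), , drop = FALSE]
    counts <- rbind(counts, matrix(merged_row, 1,
                                   dimnames = list(new_label, colnames(counts))))
    counts <- counts[order(rownames(counts)), , drop = FALSE]
    members[[a]] <- NULL; members[[b]] <- NULL
    members[[new_label]] <- new_members
    merges[[length(merges) + 1L]] <-
      tibble(merged_a = a, merged_b = b, new_label = new_label,
             score = worst$score)
  }

  label_map <- purrr::imap_dfr(members, function(m, lab) {
    tibble(old_label = m, new_label = lab)
  })
  label_map <- dplyr::arrange(label_map, old_label)
  structure(list(label_map = label_map, pseudobulk = counts,
                 merges = dplyr::bind_rows(merges)),
            class = "merge_result")
}

#' @export
print.merge_result <- function(x, ...) {
  cat("Subcluster merge:", nrow(x$label_map), "input labels ->",
      nrow(x$pseudobulk), "final labels\n")
  invisible(x)
}

#' Clustering quality scores
#'
#' Calinski-Harabasz (between/within dispersion ratio,
#' `[B/(k-1)] / [W/(n-k)]`) and Davies-Bouldin (mean over clusters of the
#' worst pairwise `(sigma_i + sigma_j) / d_ij`, with `sigma` the mean
#' Euclidean distance to the centroid and `d` the centroid distance).
#'
#' @param x Numeric matrix of embedded points (rows = observations).
#' @param labels Cluster assignment, length `nrow(x)`, at least 2 nonempty
#'   clusters.
#' @return List with `ch` and `db`.
#' @export
clustering_scores <- function(x, labels) {
  x <- as.matrix(x)
  labels <- as.character(labels)
  cl <- split(seq_len(nrow(x)), labels)
  k <- length(cl)
  if (k < 2) abort("Need at least 2 clusters.")
  n <- nrow(x)
  grand <- colMeans(x)
  cents <- t(vapply(cl, function(idx) colMeans(x[idx, , drop = FALSE]),
                    numeric(ncol(x))))
  sizes <- lengths(cl)
  B <- sum(sizes * rowSums(sweep(cents, 2, grand)^2))
  W <- sum(vapply(seq_len(k), function(i) {
    sum(sweep(x[cl[[i]], , drop = FALSE], 2, cents[i, ])^2)
  }, numeric(1)))
  ch <- (B / (k - 1)) / (W / (n - k))
  sig <- vapply(seq_len(k), function(i) {
    mean(sqrt(rowSums(sweep(x[cl[[i]], , drop = FALSE], 2, cents[i, ])^2)))
  }, numeric(1))
  db_terms <- vapply(seq_len(k), function(i) {
    max(vapply(setdiff(seq_len(k), i), function(j) {
      d <- sqrt(sum((cents[i, ] - cents[j, ])^2))
      (sig[i] + sig[j]) / d
    }, numeric(1)))
  }, numeric(1))
  list(ch = ch, db = mean(db_terms))
}

#' Marker-gene filter for enrichment input
#'
#' Keeps genes with BH-adjusted p-value strictly below `fdr_max`, mean
#' pseudobulk CPM at least `cpm_min` (inclusive), and log2 fold change
#' strictly above `lfc_min` (at least 2-fold higher expression in the
#' cluster of interest). Note the CPM bound is inclusive here, unlike the
#' strict CPM rule used for factor top genes.
#'
#' @param de_table Tibble with columns `fdr`, `mean_cpm`, `log2fc` (and any
#'   identifier columns, carried through).
#' @param fdr_max,cpm_min,lfc_min Thresholds (defaults 0.05, 10, 1).
#' @return Filtered tibble.
#' @export
marker_filter <- function(de_table, fdr_max = 0.05, cpm_min = 10,
                          lfc_min = 1) {
  dplyr::filter(as_tibble(de_table),
                fdr < fdr_max, mean_cpm >= cpm_min, log2fc > lfc_min)
}

# Default consensus classifier: nearest centroid on log1p-CPM rows,
# Pearson similarity.
centroid_classifier <- function(train_x, train_labels, query_x) {
  tx <- log1p(row_cpm(as.matrix(train_x)))
  qx <- log1p(row_cpm(as.matrix(query_x)))
  cents <- t(vapply(split(seq_len(nrow(tx)), train_labels),
                    function(idx) colMeans(tx[idx, , drop = FALSE]),
                    numeric(ncol(tx))))
  sims <- cor(t(qx), t(cents)) # queries x centroids
  rownames(cents)[max.col(sims, ties.method = "first")]
}

#' Consensus label transfer across reference splits
#'
#' Randomly partitions the reference cells into `n_splits` folds, trains one
#' classifier per fold, predicts every query cell with each, and keeps the
#' modal label only when it received at least `min_agree` of the votes;
#' otherwise the query is called `"ambiguous"`. With `n_splits = 1` and
#' `min_agree = 1` this degenerates to the plain classifier.
#'
#' @param reference_x Reference count matrix (cells x genes).
#' @param reference_labels Labels for the reference cells.
#' @param query_x Query count matrix on the same genes.
#' @param n_splits Number of reference folds (default 5).
#' @param min_agree Votes required to assign (default 4; must be
#'   <= `n_splits`).
#' @param seed Integer seed for the fold assignment.
#' @param classifier `function(train_x, train_labels, query_x)` returning
#'   predicted labels (default: nearest centroid on log1p-CPM with Pearson
#'   similarity). A fold that loses all cells of some label simply trains
#'   without it (a warning is emitted).
#' @return Tibble: `query` (rowname or index), `label` (assigned or
#'   `"ambiguous"`), `n_agree`, plus one vote column per split.
#' @export
consensus_transfer <- function(reference_x, reference_labels, query_x,
                               n_splits = 5, min_agree = 4, seed = 1,
                               classifier = centroid_classifier) {
  if (min_agree > n_splits) abort("`min_agree` must be <= `n_splits`.")
  reference_x <- as.matrix(reference_x)
  query_x <- as.matrix(query_x)
  all_labels <- unique(as.character(reference_labels))
  folds <- with_seed(seed, {
    sample(rep_len(seq_len(n_splits), nrow(reference_x)))
  })
  votes <- vapply(seq_len(n_splits), function(f) {
    idx <- which(folds == f)
    labs <- as.character(reference_labels)[idx]
    if (length(setdiff(all_labels, unique(labs)))) {
      warn(sprintf("Fold %d lacks label(s): %s", f,
                   paste(setdiff(all_labels, unique(labs)), collapse = ", ")))
    }
    classifier(reference_x[idx, , drop = FALSE], labs, query_x)
  }, character(nrow(query_x)))
  votes <- matrix(votes, nrow = nrow(query_x))
  tally <- apply(votes, 1, function(v) {
    tb <- sort(table(v), decreasing = TRUE)
    c(names(tb)[1], unname(tb[1]))
  })
  n_agree <- as.integer(tally[2, ])
  label <- ifelse(n_agree >= min_agree, tally[1, ], "ambiguous")
  out <- tibble(
    query = rownames(query_x) %||% as.character(seq_len(nrow(query_x))),
    label = label, n_agree = n_agree
  )
  colnames(votes) <- paste0("vote", seq_len(n_splits))
  dplyr::bind_cols(out, as_tibble(votes))
}
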