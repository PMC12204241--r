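test_that("the KL-NMF objective is monotone and runs are seed-deterministic", {
  fc <- generate_factor_counts(80, 40, 2, seed = 3)
  m1 <- factorize(fc$counts, K = 2, seed = 5)
  m2 <- factorize(fc$counts, K = 2, seed = 5)
  expect_equal(m1$gene_weights, m2$gene_weights)
  expect_equal(m1$cell_scores, m2$cell_scores)
  expect_true(all(diff(m1$objective) <= 1e-8))
  expect_true(all(m1$gene_weights >= 0) && all(m1$cell_scores >= 0))
  expect_equal(unname(colSums(m1$gene_weights)), rep(1, 2), tolerance = 1e-12)
  m3 <- factorize(fc$counts, K = 2, seed = 6)
  expect_false(identical(m1$cell_scores, m3$cell_scores))
})

test_that("rank-1 truth is reconstructed within 5% relative error", {
  fc <- generate_factor_counts(150, 60, 1, seed = 9)
  m <- factorize(fc$counts, K = 1, seed = 2)
  rate_true <- fc$cell_scores %*% t(fc$gene_weights)
  rate_hat <- m$cell_scores %*% t(m$gene_weights)
  rel <- norm(rate_hat - rate_true, "F") / norm(rate_true, "F")
  expect_lt(rel, 0.05)
})

test_that("fitting at the true rank beats K = 1 in held-in Poisson likelihood", {
  ll <- function(counts, model) {
    rate <- pmax(model$cell_scores %*% t(model$gene_weights), 1e-12)
    sum(stats::dpois(counts, rate, log = TRUE))
  }
  wins <- vapply(1:10, function(r) {
    fc <- generate_factor_counts(500, 200, 3, seed = 700 + r)
    m3 <- factorize(fc$counts, K = 3, seed = r)
    m1 <- factorize(fc$counts, K = 1, seed = r)
    ll(fc$counts, m3) > ll(fc$counts, m1)
  }, logical(1))
  expect_true(all(wins))
})

test_that("engine validation and custom engines work", {
  fc <- generate_factor_counts(30, 20, 1, seed = 1)
  expect_error(factorize(fc$counts, K = 25), "min\\(dim")
  expect_error(factorize(-fc$counts, K = 1), "nonnegative")
  custom <- function(counts, K, seed) {
    list(gene_weights = matrix(1, ncol(counts), K),
         cell_scores = matrix(rowSums(counts), nrow(counts), K))
  }
  m <- factorize(fc$counts, K = 1, engine = custom)
  expect_equal(m$engine, "custom")
  expect_equal(unname(colSums(m$gene_weights)), 1)
})

test_that("the factor-number rule picks the largest qualifying K", {
  # injected correlation table: largest qualifying K wins, not first crossing
  tb <- tibble::tibble(K = 2:5, max_corr = c(0.3, 0.5, 0.8, 0.6))
  expect_equal(choose_k_from_corr(tb, 0.75)$K, 5)
  expect_equal(choose_k_from_corr(tb, 0.75, first_crossing = TRUE)$K, 3)
  # K = 1 has no pairs: max correlation 0, always qualifies
  one <- tibble::tibble(K = 1, max_corr = 0)
  expect_equal(choose_k_from_corr(one, 0.75)$K, 1)
  # no qualifying K: smallest returned with the warning flag
  bad <- tibble::tibble(K = 2:4, max_corr = c(0.9, 0.95, 0.99))
  sel <- choose_k_from_corr(bad, 0.75)
  expect_equal(sel$K, 2)
  expect_true(sel$warning_flag)
  # monotone in the threshold: raising corr_max never decreases K
  ks <- vapply(c(0.2, 0.55, 0.75, 0.85, 1),
               function(cm) choose_k_from_corr(tb, cm)$K, numeric(1))
  expect_true(all(diff(ks) >= 0))
})

test_that("duplicated planted programs force near-perfect column correlation", {
  fc <- generate_factor_counts(100, 60, 3, duplicate_last = TRUE, seed = 12)
  expect_gt(cor(fc$gene_weights[, 2], fc$gene_weights[, 3]), 0.99)
  sel <- select_num_factors(fc$counts, 1:3, seed = 4)
  expect_lt(sel$K, 3) # duplication caps the chosen K below the plant
  expect_gt(sel$corr_table$max_corr[sel$corr_table$K == 3], 0.75)
})

test_that("top genes respect the strict CPM floor and tie rules", {
  gw <- matrix(c(5, 4, 3, 2, 1, 1, 1, 1,
                 1, 1, 1, 1, 2, 2, 2, 2), ncol = 2)
  rownames(gw) <- paste0("g", 1:8)
  model <- structure(list(
    gene_weights = sweep(gw, 2, colSums(gw), "/"),
    cell_scores = matrix(1, 2, 2), K = 2L, engine = "manual"),
    class = "factor_model")
  colnames(model$gene_weights) <- c("F01", "F02")
  cpm <- setNames(c(9.9, rep(20, 7)), paste0("g", 1:8))
  out <- top_genes(model, cpm, n_top = 5, cpm_min = 10)
  f1 <- out$gene[out$factor_id == "F01"]
  expect_false("g1" %in% f1) # CPM 9.9 excluded despite the largest weight
  expect_equal(f1[1], "g2")
  # ties broken lexicographically
  f2 <- out$gene[out$factor_id == "F02"]
  expect_equal(f2, c("g5", "g6", "g7", "g8", "g2"))
  # filter dominates: only 3 genes above the floor
  cpm2 <- setNames(c(rep(1, 5), rep(30, 3)), paste0("g", 1:8))
  out2 <- top_genes(model, cpm2, n_top = 5, cpm_min = 10)
  expect_equal(sort(unique(out2$gene)), c("g6", "g7", "g8"))
  expect_true(all(out2$short_list))
})

test_that("median factor scores aggregate cells per sample", {
  cs <- matrix(c(2.3, 2.3, 2.3, 1, 5, 9), ncol = 1)
  rownames(cs) <- paste0("c", 1:6)
  model <- structure(list(cell_scores = cs,
                          gene_weights = matrix(1, 3, 1), K = 1L),
                     class = "factor_model")
  colnames(model$cell_scores) <- "F01"
  map <- tibble::tibble(cell = paste0("c", 1:6),
                        sample_id = rep(c("s1", "s2"), each = 3))
  med <- median_factor_scores(model, map)
  expect_equal(med$F01[med$sample_id == "s1"], 2.3)
  expect_equal(med$F01[med$sample_id == "s2"], 5)
  expect_equal(med$n_cells, c(3, 3))
  # invariant to within-sample shuffling of cell scores
  map2 <- map[c(2, 3, 1, 6, 4, 5), ]
  expect_equal(median_factor_scores(model, map2)$F01, med$F01)
  expect_error(median_factor_scores(model, tibble::tibble(
    cell = "nope", sample_id = "s1")), "map")
})

test_that("factor associations recover a planted sample-level shift", {
  co <- generate_cohort(20, 1, seed = 41) # 60 donors -> 60 STG samples
  samples <- cohort_samples(co)
  samples <- samples[samples$region == "STG", ]
  slopes <- vapply(1:20, function(r) {
    withr::with_seed(800 + r, {
      n_cells_per <- 30
      cell_ids <- sprintf("c%05d", seq_len(nrow(samples) * n_cells_per))
      map <- tibble::tibble(
        cell = cell_ids,
        sample_id = rep(samples$sample_id, each = n_cells_per))
      impaired <- as.numeric(samples$clinical_dx %in% c("MCI", "AD"))
      shift <- rep(impaired, each = n_cells_per)
      score <- rnorm(length(cell_ids), 3, 0.8) + shift * 1.0
      cs <- matrix(pmax(score, 0), ncol = 1,
                   dimnames = list(cell_ids, "F01"))
      model <- structure(list(cell_scores = cs,
                              gene_weights = matrix(1, 2, 1), K = 1L),
                         class = "factor_model")
      assoc <- associate_factors(model, map, co)
      mean(assoc$beta_hat[assoc$trait == "dx_impaired"])
    })
  }, numeric(1))
  expect_lt(abs(mean(slopes) - 1.0), 0.2)
})

test_that("a constant factor yields a null association", {
  co <- generate_cohort(10, 1, seed = 43)
  samples <- cohort_samples(co)
  map <- tibble::tibble(cell = sprintf("c%04d", seq_len(nrow(samples) * 5)),
                        sample_id = rep(samples$sample_id, each = 5))
  cs <- matrix(2, nrow(map), 1, dimnames = list(map$cell, "F01"))
  model <- structure(list(cell_scores = cs,
                          gene_weights = matrix(1, 2, 1), K = 1L),
                     class = "factor_model")
  assoc <- suppressWarnings( # lm flags the (intended) perfect fit
    associate_factors(model, map, co, traits = "cog_decline"))
  expect_true(all(abs(assoc$beta_hat) < 1e-12))
})
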