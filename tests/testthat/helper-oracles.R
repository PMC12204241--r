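# Independent oracles used across the suite. Each re-derives a quantity by
# a route separate from the package implementation (direct formula
# evaluation, numerical optimization, or brute-force recursion).

# Numerical maximizer of the weighted binomial log-likelihood (logit link):
# an optimizer-based route independent of the package's IRLS. Non-intercept
# columns are standardized internally so BFGS converges to high precision on
# poorly scaled designs; coefficients are mapped back afterwards.
oracle_logit_mle <- function(X, y, w) {
  ctr <- colMeans(X); ctr[1] <- 0
  scl <- apply(X, 2, sd); scl[1] <- 1; scl[scl == 0] <- 1
  Z <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  nll <- function(b) {
    mu <- plogis(drop(Z %*% b))
    mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
    -sum(w * (y * log(mu) + (1 - y) * log(1 - mu)))
  }
  gr <- function(b) {
    mu <- plogis(drop(Z %*% b))
    -drop(crossprod(Z, w * (y - mu)))
  }
  fit <- optim(rep(0, ncol(Z)), nll, gr, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-16))
  b <- fit$par / scl
  b[1] <- fit$par[1] - sum((ctr / scl) * fit$par)
  b
}

# Pseudobulk pair fixture for the merge rule: a controlled number of genes
# up/down at a controlled CPM log2 fold change. Row totals are balanced by
# spreading the count difference thinly over background genes (their own
# fold changes stay far below the threshold).
make_pair <- function(n_up, n_dn, lfc = 2.1, n_genes = 60) {
  hi <- 8000; lo <- round(hi / 2^lfc)
  n_bg <- n_genes - n_up - n_dn
  a <- c(rep(hi, n_up), rep(lo, n_dn), rep(2000, n_bg))
  b <- c(rep(lo, n_up), rep(hi, n_dn), rep(2000, n_bg))
  diff <- sum(a) - sum(b)
  b[(n_up + n_dn + 1):n_genes] <- 2000 + round(diff / n_bg)
  rbind(A = a, B = b)
}

# Brute-force Lance-Williams recursion for Ward linkage applied directly to
# a dissimilarity matrix (agglomerative, merging the pair with the smallest
# current distance). Returns the sequence of merge heights.
oracle_ward_heights <- function(d) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  sizes <- rep(1, n)
  active <- seq_len(n)
  heights <- numeric(0)
  while (length(active) > 1) {
    best <- c(NA, NA); best_d <- Inf
    for (a in seq_along(active)) {
      for (b in seq_along(active)) {
        if (a < b) {
          i <- active[a]; j <- active[b]
          if (dm[i, j] < best_d) { best_d <- dm[i, j]; best <- c(i, j) }
        }
      }
    }
    i <- best[1]; j <- best[2]
    heights <- c(heights, best_d)
    ni <- sizes[i]; nj <- sizes[j]
    for (k in setdiff(active, c(i, j))) {
      nk <- sizes[k]
      dm[i, k] <- dm[k, i] <-
        ((ni + nk) * dm[i, k] + (nj + nk) * dm[j, k] - nk * dm[i, j]) /
        (ni + nj + nk)
    }
    sizes[i] <- ni + nj
    active <- setdiff(active, j)
  }
  heights
}

# Direct formula evaluation of Calinski-Harabasz and Davies-Bouldin on a
# hand-sized instance (independent loops, no shared code with the package).
oracle_ch_db <- function(x, labels) {
  labs <- unique(labels)
  k <- length(labs); n <- nrow(x)
  grand <- colMeans(x)
  B <- 0; W <- 0
  cents <- list(); sig <- numeric(k)
  for (ii in seq_along(labs)) {
    pts <- x[labels == labs[ii], , drop = FALSE]
    ce <- colMeans(pts)
    cents[[ii]] <- ce
    B <- B + nrow(pts) * sum((ce - grand)^2)
    W <- W + sum(apply(pts, 1, function(p) sum((p - ce)^2)))
    sig[ii] <- mean(apply(pts, 1, function(p) sqrt(sum((p - ce)^2))))
  }
  db <- mean(vapply(seq_len(k), function(i) {
    max(vapply(setdiff(seq_len(k), i), function(j) {
      (sig[i] + sig[j]) / sqrt(sum((cents[[i]] - cents[[j]])^2))
    }, numeric(1)))
  }, numeric(1)))
  list(ch = (B / (k - 1)) / (W / (n - k)), db = db)
}

# Small composition-with-covariates fixture shared by regression tests.
make_fit_data <- function(n = 60, seed = 42, beta = 0, p0 = 0.2) {
  withr::with_seed(seed, {
    x <- rnorm(n)
    age <- rnorm(n, 85, 6)
    sex <- factor(sample(c("F", "M"), n, replace = TRUE))
    pmi <- rgamma(n, 4, 0.5)
    total <- round(rlnorm(n, log(3000), 0.4))
    eta <- qlogis(p0) + beta * x
    p <- plogis(eta)
    y <- rbinom(n, total, p) / total
    data.frame(y = y, x = x, age_at_death = age, sex = sex, pmi = pmi,
               total = total)
  })
}
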