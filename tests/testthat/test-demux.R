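test_that("design validation enforces the no-repeated-pair constraint", {
  # donor A in two libraries is fine; pair (A,B) repeated is not
  ok <- tibble::tibble(
    library = rep(c("L1", "L2"), each = 3),
    donor_id = c("A", "B", "C", "A", "D", "E"))
  expect_true(validate_design(ok)$valid)
  bad <- tibble::tibble(
    library = rep(c("L1", "L2"), each = 3),
    donor_id = c("A", "B", "C", "A", "B", "D"))
  chk <- validate_design(bad)
  expect_false(chk$valid)
  expect_equal(chk$violations$donor1, "A")
  expect_equal(chk$violations$donor2, "B")
  # single library trivially valid
  single <- tibble::tibble(library = "L1", donor_id = c("A", "B", "C"))
  expect_true(validate_design(single)$valid)
  # structural errors
  expect_error(validate_design(tibble::tibble(
    library = "L1", donor_id = c("A", "B"))), "Structural")
  expect_error(validate_design(tibble::tibble(
    library = "L1", donor_id = c("A", "A", "B"))), "Structural")
  expect_true(validate_design(make_pool_plan(9))$valid)
})

test_that("concordance counts exact matches over shared SNPs", {
  expect_equal(concordance(c(0, 0.5, 1), c(0, 0.5, 1)), 1)
  expect_equal(concordance(c(0, 0, 1, 1), c(1, 1, 0, 0)), 0)
  expect_equal(concordance(c(0, 0.5, 1, NA), c(0, 1, NA, 0)), 0.5)
  expect_error(concordance(c(NA, NA), c(1, NA)), "No SNPs")
  expect_error(concordance(c(0, 1), c(0)), "panel")
  # random-genotype agreement matches the Hardy-Weinberg closed form
  maf <- 0.3
  probs <- c((1 - maf)^2, 2 * maf * (1 - maf), maf^2)
  expected <- sum(probs^2)
  got <- withr::with_seed(5, {
    g1 <- rbinom(4000, 2, maf) / 2
    g2 <- rbinom(4000, 2, maf) / 2
    concordance(g1, g2)
  })
  expect_lt(abs(got - expected), 3 * sqrt(expected * (1 - expected) / 4000))
})

test_that("pooled genotype generation obeys its noise closed form", {
  plan <- make_pool_plan(9)
  sim0 <- generate_pooled_genotypes(plan, n_snps = 300, error_rate = 0,
                                    seed = 3)
  expect_identical(sim0, generate_pooled_genotypes(plan, n_snps = 300,
                                                   error_rate = 0, seed = 3))
  # error_rate 0: cluster VAFs equal latent genotypes exactly; a donor's two
  # signatures are fully concordant
  for (i in seq_len(nrow(sim0$truth))) {
    rn <- paste(sim0$truth$library[i], sim0$truth$cluster[i], sep = ".")
    expect_equal(unname(sim0$vaf[rn, ]),
                 unname(sim0$genotypes[sim0$truth$donor_id[i], ]))
  }
  # noisy case: same-donor cross-library concordance ~ (1-e)^2 + e^2
  e <- 0.02
  sim <- generate_pooled_genotypes(plan, n_snps = 500, error_rate = e,
                                   seed = 4)
  expected <- (1 - e)^2 + e^2 # = 0.9604
  concs <- c()
  for (d in unique(sim$truth$donor_id)) {
    rows <- which(sim$truth$donor_id == d)
    if (length(rows) == 2) {
      rn <- paste(sim$truth$library[rows], sim$truth$cluster[rows], sep = ".")
      concs <- c(concs, concordance(sim$vaf[rn[1], ], sim$vaf[rn[2], ]))
    }
  }
  mc_sd <- sqrt(expected * (1 - expected) / 500)
  expect_lt(abs(mean(concs) - expected), 3 * mc_sd / sqrt(length(concs)) + 1e-3)
  # an invalid plan is generable but flagged
  bad <- tibble::tibble(
    library = rep(c("L1", "L2"), each = 3),
    donor_id = c("A", "B", "C", "A", "B", "D"),
    region = "STG")
  simbad <- generate_pooled_genotypes(bad, n_snps = 50, seed = 1)
  expect_false(simbad$design_valid)
  expect_error(generate_pooled_genotypes(plan, error_rate = 0.5), "0.5")
})

test_that("identity assignment recovers all donors on a clean design", {
  plan <- make_pool_plan(9)
  sim <- generate_pooled_genotypes(plan, n_snps = 500, error_rate = 0,
                                   seed = 11)
  asg <- assign_identities(sim$vaf, sim$clusters, plan)
  expect_equal(asg$donor_id, sim$truth$donor_id)
  # permutation invariance: relabel libraries' row order
  perm <- withr::with_seed(2, sample(nrow(sim$vaf)))
  asg2 <- assign_identities(sim$vaf[perm, ], sim$clusters[perm, ], plan)
  expect_equal(asg2$donor_id, sim$truth$donor_id[perm])
})

test_that("raising min_concordance never assigns more clusters", {
  plan <- make_pool_plan(9)
  sim <- generate_pooled_genotypes(plan, n_snps = 400, error_rate = 0.05,
                                   seed = 21)
  n_assigned <- vapply(c(0.7, 0.85, 0.95, 0.999), function(th) {
    sum(!is.na(assign_identities(sim$vaf, sim$clusters, plan,
                                 min_concordance = th)$donor_id))
  }, numeric(1))
  expect_true(all(diff(n_assigned) <= 0))
})

test_that("fingerprint ambiguity and unassignable components are handled", {
  # donors E and F appear only in L3: any singleton there matches both
  plan <- tibble::tibble(
    library = rep(c("L1", "L2", "L3"), each = 3),
    donor_id = c("A", "B", "C", "A", "D", "G", "E", "F", "D"))
  expect_true(validate_design(plan)$valid)
  sim <- generate_pooled_genotypes(plan, n_snps = 300, error_rate = 0,
                                   seed = 31)
  expect_error(assign_identities(sim$vaf, sim$clusters, plan),
               "Ambiguous fingerprint")

  # genetically identical donors merge into one component whose fingerprint
  # matches no single donor: left unassigned, others still recovered
  plan2 <- make_pool_plan(9)
  sim2 <- generate_pooled_genotypes(plan2, n_snps = 300, error_rate = 0,
                                    seed = 32)
  twin_of <- sim2$truth$donor_id == "D001"
  target <- sim2$truth$donor_id == "D005"
  sim2$vaf[which(target), ] <- sim2$vaf[which(twin_of), ][
    seq_len(sum(target)), ]
  asg <- assign_identities(sim2$vaf, sim2$clusters, plan2)
  merged <- sim2$truth$donor_id %in% c("D001", "D005")
  expect_true(all(is.na(asg$donor_id[merged])))
  expect_equal(asg$donor_id[!merged], sim2$truth$donor_id[!merged])
})
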