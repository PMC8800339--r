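test_that("hierarchical frequencies: degenerate copies and point-mass MAF", {
  spec <- flat_spec(K = 2, F = 0, n = 5, n_snps = 100,
                    maf_range = c(0.3, 0.3), seed = 4)
  fr <- draw_hierarchical_frequencies(spec)
  expect_equal(unname(fr$ancestral), rep(0.3, 100))
  # F_c = 0 and F_s = 0: every level equals the ancestral p exactly
  expect_equal(unname(fr$continent["C1", ]), fr$ancestral)
  expect_equal(unname(fr$subpop["P2", ]), fr$ancestral)
})

test_that("Balding-Nichols divergence recovers F on latent frequencies", {
  # Hudson ratio-of-averages on the latent frequency vectors themselves,
  # with huge n so the finite-sample correction vanishes: expected F
  spec <- flat_spec(K = 2, F = 0.05, n = 2, n_snps = 20000, seed = 11)
  fr <- draw_hierarchical_frequencies(spec)
  p1 <- fr$continent[1, ]; p2 <- fr$continent[2, ]
  hc <- hudson_components(p1, 1e9, p2, 1e9)
  est <- sum(hc$numerator) / sum(hc$denominator)
  expect_lt(abs(est - 0.05), 0.01)
})

test_that("genotype sampling matches the drawn frequencies", {
  spec <- flat_spec(K = 1, F = 0, n = 5000, n_snps = 10, seed = 2)
  cohort <- simulate_cohort(spec)
  p <- cohort$freqs$subpop["P1", ]
  f_hat <- colMeans(cohort$genotypes$calls) / 2
  se <- sqrt(p * (1 - p) / (2 * 5000))
  expect_true(all(abs(f_hat - p) < 3.5 * se))
})

test_that("pure-continent admixture collapses to subpopulation sampling", {
  # alpha heavily concentrated on continent 1 -> q ~ (1,0); allele
  # frequencies of the admixed block match continent 1's within 3.5 SE
  conts <- list(
    list(name = "C1", F = 0.2,
         subpops = list(list(name = "P1", F = 0, n = 2, region = "R1"))),
    list(name = "C2", F = 0.2,
         subpops = list(list(name = "P2", F = 0, n = 2, region = "R2"))))
  spec <- population_spec(conts, n_snps = 30, seed = 8,
                          admixed_blocks = list(list(n = 2000,
                                                     alpha = c(1e6, 1e-3))))
  cohort <- simulate_cohort(spec)
  adm <- cohort$truth$sample_id[grepl("^ADMIX", cohort$truth$subpop)]
  g <- cohort$genotypes$calls[match(adm, cohort$genotypes$samples$id), ]
  pc <- cohort$freqs$continent["C1", ]
  f_hat <- colMeans(g) / 2
  se <- sqrt(pc * (1 - pc) / (2 * length(adm)))
  expect_true(all(abs(f_hat - pc) < 3.5 * se))
})

test_that("simulation is byte-identical under the same seed", {
  spec <- default_rehearsal_spec(n_snps = 300, n_per_subpop = 5,
                                 n_reference = 4, n_admixed = 5,
                                 relative_pairs = 2, seed = 99)
  a <- simulate_cohort(spec)
  b <- simulate_cohort(spec)
  expect_identical(a$genotypes$calls, b$genotypes$calls)
  expect_identical(a$truth, b$truth)
  expect_identical(a$truth_relative_pairs, b$truth_relative_pairs)
})

test_that("truth q rows sum to one", {
  spec <- default_rehearsal_spec(n_snps = 200, n_per_subpop = 5,
                                 n_reference = 4, n_admixed = 20,
                                 relative_pairs = 2, seed = 3)
  cohort <- simulate_cohort(spec)
  qs <- rowSums(cohort$truth[grep("^q\\.", names(cohort$truth))])
  expect_true(all(abs(qs - 1) < 1e-12))
})

test_that("relatives: Mendelian transmission and truth bookkeeping", {
  spec <- flat_spec(K = 1, F = 0, n = 40, n_snps = 20000, seed = 6)
  base <- simulate_cohort(spec)
  set.seed(42)
  cohort <- add_relatives(base, 3)
  expect_equal(nrow(cohort$truth_relative_pairs), 6)
  expect_equal(nrow(cohort$genotypes$calls), 43)
  gm <- cohort$genotypes
  pr <- cohort$truth_relative_pairs
  child <- pr$id1[1]
  parents <- pr$id2[pr$id1 == child]
  gc <- gm$calls[child, ]
  gp1 <- gm$calls[parents[1], ]; gp2 <- gm$calls[parents[2], ]
  # both parents hom-ref -> offspring 0; both hom-alt -> offspring 2
  expect_true(all(gc[gp1 == 0 & gp2 == 0] == 0))
  expect_true(all(gc[gp1 == 2 & gp2 == 2] == 2))
  # genome-wide relatedness about 0.5 on the GRM scale
  rel <- grm(gm, maf_floor = 0.05)
  i <- match(child, rel$ids); j <- match(parents[1], rel$ids)
  expect_lt(abs(rel$matrix[i, j] - 0.5), 0.05)
  # n_pairs = 0 is the identity
  expect_identical(add_relatives(base, 0), base)
})

test_that("birth labels: concordance and missingness behave as stated", {
  spec <- subpop_spec(n_sub = 3, F_s = 0, n = 400, n_snps = 10,
                      seed = 21, label_concordance = 0.8)
  cohort <- simulate_cohort(spec)
  conc <- mean(cohort$truth$obs_region == cohort$truth$region)
  se <- sqrt(0.8 * 0.2 / nrow(cohort$truth))
  expect_lt(abs(conc - 0.8), 3 * se)

  # full concordance gives a block-diagonal subpop x region table
  spec1 <- subpop_spec(n_sub = 3, F_s = 0, n = 30, n_snps = 10,
                       seed = 22, label_concordance = 1)
  c1 <- simulate_cohort(spec1)
  tab <- table(c1$truth$subpop, c1$truth$obs_region)
  expect_equal(sum(diag(tab)), sum(tab))

  # all labels missing: downstream CA must refuse the empty table
  spec0 <- subpop_spec(n_sub = 2, F_s = 0, n = 20, n_snps = 10,
                       seed = 23, missing_label_fraction = 1)
  c0 <- simulate_cohort(spec0)
  expect_true(all(is.na(c0$truth$obs_region)))
  expect_error(build_contingency(c0$truth$subpop, c0$truth$obs_region),
               "no samples")
})

test_that("LD-block mode plants correlated duplicates", {
  spec <- subpop_spec(n_sub = 1, F_s = 0, n = 150, n_snps = 400, seed = 5,
                      ld_tag_fraction = 0.25, ld_flip_prob = 0.02)
  cohort <- simulate_cohort(spec)
  gm <- cohort$genotypes
  expect_equal(ncol(gm$calls), 500)
  dups <- grep("_dup$", gm$variants$id, value = TRUE)
  r2 <- vapply(dups, function(d)
    ld_r2(gm$calls[, sub("_dup$", "", d)], gm$calls[, d]), 0)
  expect_gt(mean(r2), 0.8)                 # about (1 - 2 eps)^2 = 0.92
})
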