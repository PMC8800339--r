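test_that("reference_frequencies: clamping, warnings, count oracle", {
  calls <- matrix(c(0L, 0L, 2L, 2L, 1L, 1L, NA, NA), 2, 4)
  gm <- gm_from_calls(calls)
  gm$samples$population_label <- c("G1", "G1")
  expect_warning(model <- reference_frequencies(gm), "all-missing")
  expect_equal(unname(model$f[1, ]), c(1e-6, 1 - 1e-6, 0.5, 0.5))

  set.seed(4)
  calls2 <- matrix(sample(c(0:2, NA), 120, TRUE, prob = c(.3, .3, .3, .1)),
                   6, 20)
  gm2 <- gm_from_calls(calls2)
  gm2$samples$population_label <- rep(c("A", "B"), each = 3)
  m2 <- suppressWarnings(reference_frequencies(gm2))
  for (j in 1:20) {
    obs <- calls2[1:3, j][!is.na(calls2[1:3, j])]
    expected <- if (length(obs)) sum(obs) / (2 * length(obs)) else 0.5
    expect_equal(m2$f["A", j], min(max(expected, 1e-6), 1 - 1e-6))
  }
  gm$samples$population_label <- c("G1", NA)
  expect_error(reference_frequencies(gm), "fewer than 2")
})

test_that("EM recovers pure ancestry, keeps the simplex, and is monotone", {
  spec <- flat_spec(K = 4, F = 0.1, n = 40, n_snps = 5000, seed = 17)
  cohort <- simulate_cohort(spec)
  gm <- cohort$genotypes
  gm$samples$population_label <- cohort$truth$continent
  model <- reference_frequencies(gm)
  # fit ten held-out-style individuals from continent 1
  ids <- cohort$truth$sample_id[cohort$truth$continent == "C1"][1:10]
  fit <- fit_admixture(gm, model, sample_ids = ids, max_iter = 300)
  expect_true(all(fit$q[, "C1"] > 0.95))
  expect_true(all(abs(rowSums(fit$q) - 1) < 1e-8))
  expect_true(all(diff(fit$loglik) >= -1e-6))
})

test_that("duplicated reference population: pooled q still identified", {
  spec <- flat_spec(K = 2, F = 0.15, n = 40, n_snps = 4000, seed = 19)
  cohort <- simulate_cohort(spec)
  gm <- cohort$genotypes
  labels <- cohort$truth$continent
  model <- reference_frequencies(gm, groups = split(gm$samples$id, labels))
  # duplicate C1's frequency row: split is non-identifiable but the pool
  # must recover the original C1 proportion
  model$f <- rbind(model$f, C1dup = model$f["C1", ])
  model$populations <- c(model$populations, "C1dup")
  ids <- cohort$truth$sample_id[labels == "C1"][1:8]
  fit <- fit_admixture(gm, model, sample_ids = ids, max_iter = 300)
  pooled <- fit$q[, "C1"] + fit$q[, "C1dup"]
  expect_true(all(pooled > 0.95))
  expect_true(fit$converged || fit$iterations == 300)
})

test_that("K = 1 collapses to q = 1 immediately", {
  gm <- gm_from_calls(matrix(c(0L, 1L, 2L, NA), 2, 2))
  model <- structure(list(populations = "ONLY",
                          f = matrix(0.4, 1, 2,
                                     dimnames = list("ONLY", NULL)),
                          variant_ids = gm$variants$id),
                     class = "ancestry_model")
  fit <- fit_admixture(gm, model)
  expect_equal(unname(fit$q[, 1]), c(1, 1))
  expect_equal(fit$iterations, 1L)
})

test_that("permuting reference populations permutes q columns", {
  spec <- flat_spec(K = 3, F = 0.1, n = 30, n_snps = 2000, seed = 23)
  cohort <- simulate_cohort(spec)
  gm <- cohort$genotypes
  model <- reference_frequencies(
    gm, groups = split(gm$samples$id, cohort$truth$continent))
  perm <- c(3, 1, 2)
  model_p <- model
  model_p$f <- model$f[perm, ]
  model_p$populations <- model$populations[perm]
  ids <- gm$samples$id[1:5]
  f1 <- fit_admixture(gm, model, sample_ids = ids, max_iter = 100)
  f2 <- fit_admixture(gm, model_p, sample_ids = ids, max_iter = 100)
  expect_equal(f2$q, f1$q[, model_p$populations])
})

test_that("assign_cag applies an inclusive threshold", {
  q <- rbind(a = c(0.80, 0.10, 0.05, 0.05),
             b = c(0.79, 0.21, 0.00, 0.00),
             c = c(0.25, 0.25, 0.25, 0.25))
  colnames(q) <- c("AFR", "EUR", "SAS", "EAS")
  lab <- assign_cag(q, threshold = 0.8)
  expect_equal(unname(lab), c("AFR", "unassigned", "unassigned"))
})

test_that("reference pairwise Fst behaves on identical and diverged panels", {
  spec <- flat_spec(K = 2, F = 0.1, n = 60, n_snps = 20000, seed = 29)
  cohort <- simulate_cohort(spec)
  gm <- cohort$genotypes
  gm$samples$population_label <- cohort$truth$continent
  res <- reference_pairwise_fst(gm)
  expect_lt(abs(unname(res$mean) - 0.1), 0.01)

  # identical reference groups: mean 0 (split halves of one population)
  spec0 <- flat_spec(K = 1, F = 0, n = 80, n_snps = 20000, seed = 31)
  gm0 <- simulate_cohort(spec0)$genotypes
  gm0$samples$population_label <- rep(c("H1", "H2"), 40)
  res0 <- reference_pairwise_fst(gm0)
  expect_lt(abs(unname(res0$mean)), 0.005)
})

test_that("four panels from one ancestor average near their divergence", {
  spec <- flat_spec(K = 4, F = 0.1, n = 50, n_snps = 20000, seed = 37)
  cohort <- simulate_cohort(spec)
  gm <- cohort$genotypes
  gm$samples$population_label <- cohort$truth$continent
  res <- reference_pairwise_fst(gm)
  expect_equal(sum(upper.tri(res$fst$fst)), 6)
  expect_lt(abs(unname(res$mean) - 0.1), 0.01)
})

test_that("Q table export round-trips proportions and labels", {
  spec <- flat_spec(K = 2, F = 0.1, n = 20, n_snps = 1000, seed = 41)
  cohort <- simulate_cohort(spec)
  gm <- cohort$genotypes
  gm$samples$population_label <- cohort$truth$continent
  model <- reference_frequencies(gm)
  fit <- fit_admixture(gm, model, sample_ids = gm$samples$id[1:5],
                       max_iter = 100)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_q_table(fit, f)
  back <- read.delim(f)
  expect_equal(back$id, rownames(fit$q))
  expect_equal(back$q.C1, unname(fit$q[, "C1"]), tolerance = 1e-6)
  expect_true(all(back$cag %in% c("C1", "C2", "unassigned")))
})
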