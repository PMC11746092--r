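test_that("genotype sampling matches Hardy-Weinberg frequencies and is reproducible", {
  g <- sample_genotypes(100000L, 0.5, seed = 7L)
  counts <- tabulate(g + 1L, 3L) / length(g)
  # binomial 3-sd bands around (0.25, 0.5, 0.25)
  for (i in 1:3) {
    p <- c(0.25, 0.5, 0.25)[i]
    expect_lt(abs(counts[i] - p), 3 * sqrt(p * (1 - p) / length(g)))
  }
  expect_equal(sample_genotypes(50L, c(0, 0.3), seed = 1L)[, 1],
               rep(0L, 50L), ignore_attr = TRUE)
  expect_identical(sample_genotypes(200L, c(0.1, 0.5), seed = 9L),
                   sample_genotypes(200L, c(0.1, 0.5), seed = 9L))
  expect_error(sample_genotypes(10L, 0.8), "0, 0.5")
})

test_that("linear model sampling and logistic probabilities follow closed forms", {
  m <- sample_linear_model(25L, seed = 3L)
  expect_length(m$coefficients, 25L)
  expect_identical(m, sample_linear_model(25L, seed = 3L))
  expect_equal(sample_linear_model(5L, coefficient_sd = 0, seed = 1L)$coefficients,
               rep(0, 5))

  zero <- sample_linear_model(3L, coefficient_sd = 0, seed = 1L)
  expect_equal(linear_prob(zero, matrix(0:2, 4, 3)), rep(0.5, 4))
  m2 <- structure(list(intercept = -1, coefficients = 0.5,
                       coefficient_sd = 0.5), class = "linear_effect_model")
  expect_equal(linear_prob(m2, 2), 0.5)
  m3 <- structure(list(intercept = 0, coefficients = log(2),
                       coefficient_sd = 0.5), class = "linear_effect_model")
  expect_equal(linear_prob(m3, 1), 2 / 3)
  # numerically stable at extreme logits
  m4 <- structure(list(intercept = 500, coefficients = numeric(0),
                       coefficient_sd = 0.5), class = "linear_effect_model")
  expect_equal(linear_prob(m4, matrix(numeric(0), 1, 0)), 1)
})

test_that("mixed probability is the affine alpha blend of its two parts", {
  tab <- solve_penetrance("threshold", c(0.25, 0.25), 0.25)
  lin <- sample_linear_model(4L, seed = 2L)
  g <- sample_genotypes(50L, rep(0.4, 6), seed = 5L)
  p_lin <- linear_prob(lin, g[, 1:4])
  m0 <- mixed_phenotype_model(0, lin, tab, 1:4, 5:6)
  m1 <- mixed_phenotype_model(1, lin, tab, 1:4, 5:6)
  idx <- g[, 5] * 3 + g[, 6] + 1
  expect_equal(mixed_prob(m0, g), unname(tab$values[idx]))
  expect_equal(mixed_prob(m1, g), unname(p_lin))
  for (a in c(0.2, 0.5, 0.8)) {
    ma <- mixed_phenotype_model(a, lin, tab, 1:4, 5:6)
    expect_equal(mixed_prob(ma, g),
                 a * mixed_prob(m1, g) + (1 - a) * mixed_prob(m0, g))
  }
  expect_error(mixed_phenotype_model(0.5, lin, tab, 1:4, 4:5), "disjoint")
})

test_that("phenotype assignment is Bernoulli with the requested probabilities", {
  expect_equal(assign_phenotypes(rep(0, 100)), rep(0L, 100))
  expect_equal(assign_phenotypes(rep(1, 100)), rep(1L, 100))
  y <- assign_phenotypes(rep(0.3, 100000L), seed = 11L)
  expect_lt(abs(mean(y) - 0.3), 3 * sqrt(0.3 * 0.7 / 1e5))
  expect_error(assign_phenotypes(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("balanced cohorts hit exact case/control quotas with intact noise SNPs", {
  tab <- solve_penetrance("threshold", c(0.25, 0.25), 0.25)
  model <- mixed_phenotype_model(0, sample_linear_model(0, seed = 0L), tab,
                                 integer(0), c(3L, 7L))
  ds <- balanced_dataset(model, 2000L, 10L, seed = 21L)
  expect_equal(sum(ds$labels == 1L), 1000L)
  expect_equal(sum(ds$labels == 0L), 1000L)
  expect_equal(dim(ds$genotypes), c(2000L, 10L))
  expect_true(all(ds$genotypes %in% 0:2))
  # determinism
  ds2 <- balanced_dataset(model, 2000L, 10L, seed = 21L)
  expect_identical(ds$genotypes, ds2$genotypes)
  expect_identical(ds$labels, ds2$labels)
  # noise columns carry no association with the label (chi-square sanity)
  noise_col <- ds$genotypes[, 1L]
  pval <- suppressWarnings(chisq.test(table(noise_col, ds$labels))$p.value)
  expect_gt(pval, 1e-4)
})

test_that("balanced sampling preserves the conditional case probability profile", {
  # after balancing, P(g | case) must follow P(g) p_g / pi; compare the
  # empirical genotype-tuple distribution among cases with that oracle
  tab <- solve_penetrance("multiplicative", c(0.25, 0.25), 0.25)
  model <- mixed_phenotype_model(0, sample_linear_model(0, seed = 0L), tab,
                                 integer(0), 1:2)
  n <- 200000L
  ds <- balanced_dataset(model, n, 2L, seed = 33L)
  idx <- ds$genotypes[, 1L] * 3L + ds$genotypes[, 2L] + 1L
  # tuple-index order: g1 slow, g2 fast
  w <- rep(hwe_genotype_freqs(0.25), each = 3) * rep(hwe_genotype_freqs(0.25), 3)
  p_case <- w * tab$values / sum(w * tab$values)
  emp <- tabulate(idx[ds$labels == 1L], 9L) / (n / 2L)
  for (cell in 1:9) {
    se <- sqrt(p_case[cell] * (1 - p_case[cell]) / (n / 2L))
    expect_lt(abs(emp[cell] - p_case[cell]), 4 * se + 1e-6)
  }
})

test_that("infeasible class balance is reported", {
  tiny <- penetrance_table(2L, c(0.25, 0.25), rep(1e-6, 9))
  model <- mixed_phenotype_model(0, sample_linear_model(0, seed = 0L), tiny,
                                 integer(0), 1:2)
  expect_error(balanced_dataset(model, 2000L, 4L, seed = 1L,
                                max_batches = 6L),
               "infeasible|quota")
})

test_that("alpha sweep shares one genotype matrix across label vectors", {
  tab <- solve_penetrance("threshold", c(0.25, 0.25), 0.25)
  lin <- sample_linear_model(5L, seed = 4L)
  g <- sample_genotypes(500L, rep(0.4, 8), seed = 6L)
  sweep <- alpha_sweep(g, lin, tab, alphas = seq(1, 0, length.out = 10L),
                       seed = 13L)
  expect_length(sweep, 10L)
  for (ds in sweep) expect_identical(ds$genotypes, g)
  sweep2 <- alpha_sweep(g, lin, tab, alphas = seq(1, 0, length.out = 10L),
                        seed = 13L)
  expect_identical(lapply(sweep, `[[`, "labels"),
                   lapply(sweep2, `[[`, "labels"))
  # alpha = 1: labels independent of the epistatic columns
  ds1 <- sweep[[1L]]
  tab1 <- table(ds1$genotypes[, 6L], ds1$labels)
  expect_gt(suppressWarnings(chisq.test(tab1)$p.value), 1e-4)
})

test_that("the GAMETES-style experiment produces the replicate design", {
  exp <- gametes_experiment("threshold", replicates = 3L, n = 400L,
                            total_snps = 12L, seed = 17L)
  expect_length(exp$datasets, 3L)
  expect_equal(heritability(exp$table), 0.25, tolerance = 1e-6)
  for (ds in exp$datasets) {
    expect_equal(sum(ds$labels), 200L)
    expect_equal(ncol(ds$genotypes), 12L)
    expect_equal(ds$provenance$alpha, 0)
  }
  # replicates differ from each other
  expect_false(identical(exp$datasets[[1L]]$genotypes,
                         exp$datasets[[2L]]$genotypes))
})

test_that("theoretical AUC: degenerate cases, MC agreement, and monotonicity", {
  lin0 <- sample_linear_model(0, seed = 0L)
  const <- penetrance_table(2L, c(0.5, 0.5), rep(0.4, 9))
  m_const <- mixed_phenotype_model(0, lin0, const, integer(0), 1:2)
  expect_equal(theoretical_auc(m_const), 0.5)

  # deterministic table at prevalence 1/2: perfect separation
  det <- penetrance_table(2L, c(0.5, 0.5), rep(c(1, 0), length.out = 9))
  m_det <- mixed_phenotype_model(0, lin0, det, integer(0), 1:2)
  expect_equal(theoretical_auc(m_det), 1)

  # exact vs Monte-Carlo on a solved table
  tab <- solve_penetrance("additive", c(0.25, 0.25), 0.25)
  m <- mixed_phenotype_model(0, lin0, tab, integer(0), 1:2)
  expect_lt(abs(theoretical_auc(m) -
                  theoretical_auc(m, "monte_carlo", 2e5, seed = 5L)), 0.01)

  # AUC never below 1/2 and monotone in the effect parameter
  prev_auc <- 0.5
  for (e in c(0.05, 0.2, 0.5, 1, 2)) {
    t2 <- marchini_table(epistasis_form("threshold", 0.2, e), c(0.25, 0.25))
    a <- theoretical_auc(mixed_phenotype_model(0, lin0, t2, integer(0), 1:2))
    expect_gte(a, 0.5)
    expect_gte(a, prev_auc - 1e-12)
    prev_auc <- a
  }

  # capacity guard for the exact method
  lin_big <- sample_linear_model(15L, seed = 1L)
  m_big <- mixed_phenotype_model(0.5, lin_big, tab, 1:15, 16:17)
  expect_error(theoretical_auc(m_big, "exact"), "monte_carlo")
})

test_that("empirical AUC of the ground-truth score converges to the exact value", {
  tab <- solve_penetrance("multiplicative", c(0.25, 0.25), 0.25)
  lin <- sample_linear_model(3L, seed = 8L)
  m <- mixed_phenotype_model(0.5, lin, tab, 1:3, 4:5)
  exact <- theoretical_auc(m)
  g <- sample_genotypes(200000L, c(rep(0.5, 3), tab$mafs), seed = 19L)
  p <- mixed_prob(m, g)
  y <- assign_phenotypes(p, seed = 23L)
  expect_lt(abs(epibench:::auc_rank(y, p) - exact), 0.01)
})

test_that("dataset files round-trip through the tab-delimited format", {
  ds <- tiny_epistatic_dataset(n = 200L, total_snps = 6L, seed = 2L)
  path <- tempfile(fileext = ".tsv")
  write_dataset(ds, path)
  header <- strsplit(readLines(path, n = 1L), "\t")[[1L]]
  expect_equal(header[length(header)], "Class")
  back <- read_dataset(path)
  expect_equal(unname(back$genotypes), unname(ds$genotypes))
  expect_equal(back$labels, ds$labels)
  expect_true(file.exists(paste0(path, ".provenance")))
})
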