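test_that("Hardy-Weinberg genotype frequencies follow the closed form", {
  expect_equal(hwe_genotype_freqs(0.5), c(0.25, 0.5, 0.25))
  expect_equal(hwe_genotype_freqs(0), c(1, 0, 0))
  expect_equal(hwe_genotype_freqs(0.25), c(0.5625, 0.375, 0.0625))
  for (q in c(0.05, 0.17, 0.33, 0.5)) {
    expect_equal(sum(hwe_genotype_freqs(q)), 1)
  }
  expect_error(hwe_genotype_freqs(0.7), "0, 0.5")
  expect_error(hwe_genotype_freqs(-0.1), "0, 0.5")
})

test_that("Marchini-form tables have the form-specific cell structure", {
  # zero effect: constant table at the baseline for every form
  for (nm in c("additive", "multiplicative", "threshold")) {
    tab <- marchini_table(epistasis_form(nm, 0.3, 0), c(0.25, 0.25))
    expect_equal(unname(tab$values), rep(0.3, 9))
  }
  # threshold: exactly two distinct penetrance levels (minor/major effect)
  thr <- marchini_table(epistasis_form("threshold", 0.2, 1.5), c(0.3, 0.3))
  expect_length(unique(thr$values), 2L)
  # multiplicative: all cells with a homozygous-reference locus share the
  # baseline value
  mul <- marchini_table(epistasis_form("multiplicative", 0.05, 0.8),
                        c(0.3, 0.3))
  ref <- mul$tuples[, 1] == 0 | mul$tuples[, 2] == 0
  expect_equal(unname(unique(mul$values[ref])), 0.05)
  expect_true(all(mul$values[!ref] > 0.05))
  # additive: penetrance strictly increasing in the total allele count
  add <- marchini_table(epistasis_form("additive", 0.05, 0.5), c(0.3, 0.3))
  counts <- rowSums(add$tuples)
  expect_equal(order(add$values), order(counts + seq_along(counts) * 1e-9))
})

test_that("infeasible form parameters raise an error naming the cell", {
  expect_error(marchini_table(epistasis_form("additive", 0.5, 1), c(0.25, 0.25)),
               "2,2")
  expect_error(marchini_table(epistasis_form("threshold", 0.9, 0.5), c(0.25, 0.25)),
               "infeasible")
})

test_that("penetrance cells are monotone non-decreasing in effect", {
  for (nm in c("additive", "multiplicative", "threshold")) {
    for (order_mafs in list(c(0.25, 0.25), c(0.1, 0.4, 0.25))) {
      effs <- c(0, 0.1, 0.3, 0.6)
      base <- 0.9 * (1 + max(effs))^(-max_exponent(nm, length(order_mafs)))
      prev_vals <- NULL
      for (e in effs) {
        tab <- marchini_table(epistasis_form(nm, base, e), order_mafs)
        causal <- apply(tab$tuples >= 1, 1, all)
        if (!is.null(prev_vals)) {
          expect_true(all(tab$values[causal] >= prev_vals[causal] - 1e-12))
        }
        prev_vals <- tab$values
      }
    }
  }
})

test_that("prevalence and heritability match literal enumeration oracles", {
  set.seed(42)
  for (i in 1:10) {
    order <- sample(2:3, 1)
    mafs <- runif(order, 0.05, 0.5)
    nm <- sample(c("additive", "multiplicative", "threshold"), 1)
    eff <- runif(1, 0, 0.5)
    base <- runif(1, 0.2, 0.95) * (1 + eff)^(-max_exponent(nm, order))
    tab <- marchini_table(epistasis_form(nm, base, eff), mafs)
    expect_equal(prevalence(tab), prevalence_bruteforce(tab),
                 tolerance = 1e-12)
    expect_equal(heritability(tab), heritability_bruteforce(tab),
                 tolerance = 1e-12)
  }
  # hand-checkable corners
  const <- penetrance_table(2L, c(0.5, 0.5), rep(0.37, 9))
  expect_equal(prevalence(const), 0.37)
  expect_equal(heritability(const), 0)
  # only the double-homozygote cell penetrant: prevalence = P(g=2)^2
  corner <- penetrance_table(2L, c(0.5, 0.5), c(rep(0, 8), 1))
  expect_equal(prevalence(corner), 0.25^2)
  expect_equal(prevalence(corner), prevalence_bruteforce(corner))
})

test_that("deterministic half-split table has heritability one", {
  # penetrance 0/1 on the allele-parity split: prevalence 1/2 at MAF 0.5,
  # so all trait variance is genetic
  vals <- rep(c(1, 0), length.out = 9)  # 1 where g1 + g2 is even
  tab <- penetrance_table(2L, c(0.5, 0.5), vals)
  expect_equal(prevalence(tab), 0.5)
  expect_equal(heritability(tab), 1)
})

test_that("prevalence and heritability are symmetric under locus permutation", {
  tab <- marchini_table(epistasis_form("multiplicative", 0.04, 0.6),
                        c(0.1, 0.35))
  # swap loci: reorder values so locus 1 and 2 exchange roles
  perm_vals <- tab$values[order(tab$tuples[, 2], tab$tuples[, 1])]
  swapped <- penetrance_table(2L, rev(tab$mafs), perm_vals)
  expect_equal(prevalence(swapped), prevalence(tab), tolerance = 1e-14)
  expect_equal(heritability(swapped), heritability(tab), tolerance = 1e-14)
})

test_that("solver hits target heritability and maximizes prevalence on the boundary", {
  tab <- solve_penetrance("threshold", c(0.25, 0.25), 0.25)
  expect_equal(heritability(tab), 0.25, tolerance = 1e-6)
  # max-prevalence solution sits on the feasibility boundary: top cell = 1
  expect_equal(max(tab$values), 1, tolerance = 1e-9)
  # h2 -> 0 limit gives a near-constant table
  small <- solve_penetrance("additive", c(0.25, 0.25), 1e-4)
  expect_lt(diff(range(small$values)) / max(small$values), 0.2)
  expect_equal(heritability(small), 1e-4, tolerance = 1e-8)
})

test_that("extreme heritability targets either solve exactly or report the maximum", {
  # on the penetrance scale the boundary family approaches a
  # deterministic 0/1 trait, so even very high targets remain solvable
  high <- solve_penetrance("threshold", c(0.5, 0.5), 0.999)
  expect_equal(heritability(high), 0.999, tolerance = 1e-6)
  # beyond the numeric search range the solver reports what is achievable
  err <- tryCatch(solve_penetrance("threshold", c(0.5, 0.5), 1 - 1e-12),
                  error = function(e) conditionMessage(e))
  expect_match(err, "maximum achievable")
  max_h2 <- as.numeric(sub(".*maximum achievable is ", "", err))
  expect_gt(max_h2, 0.99)
  expect_lte(max_h2, 1)
})

test_that("bundled example tables parse and carry their stated heritability", {
  for (f in c("additive", "multiplicative", "threshold")) {
    path <- system.file("extdata", paste0("table_", f, "_h25_maf25.txt"),
                        package = "epibench")
    tab <- read_penetrance_table(path)
    expect_equal(heritability(tab), 0.25, tolerance = 1e-6)
    expect_equal(tab$mafs, c(0.25, 0.25))
  }
})

test_that("penetrance table file round-trips and rejects malformed input", {
  tab <- solve_penetrance("additive", c(0.25, 0.25), 0.25)
  path <- tempfile(fileext = ".txt")
  write_penetrance_table(tab, path)
  back <- read_penetrance_table(path)
  expect_equal(back$values, tab$values, tolerance = 1e-11)
  expect_equal(back$mafs, tab$mafs)

  lines <- readLines(path)
  writeLines(lines[1:10], path)  # 8 cells for order 2
  expect_error(read_penetrance_table(path), "expected 9 genotype lines")

  lines2 <- lines
  lines2[4] <- sub("\t.*", "\t1.2", lines2[4])
  writeLines(lines2, path)
  expect_error(read_penetrance_table(path), "outside \\[0, 1\\]")
})
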