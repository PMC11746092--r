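# Independent brute-force oracles used across the suite. These stay
# deliberately literal (nested loops, all-pairs sums) so they share no
# code with the vectorized implementations they check.

# All-pairs AUC with half credit for ties.
auc_bruteforce <- function(labels, scores) {
  cases <- scores[labels == 1]
  controls <- scores[labels == 0]
  total <- 0
  for (ci in cases) {
    for (co in controls) {
      total <- total + if (ci > co) 1 else if (ci == co) 0.5 else 0
    }
  }
  total / (length(cases) * length(controls))
}

# Literal enumeration of prevalence over all genotype tuples.
prevalence_bruteforce <- function(table) {
  freqs <- lapply(table$mafs, function(q) c((1 - q)^2, 2 * q * (1 - q), q^2))
  total <- 0
  for (i in seq_len(nrow(table$tuples))) {
    w <- 1
    for (l in seq_len(table$order)) {
      w <- w * freqs[[l]][table$tuples[i, l] + 1]
    }
    total <- total + w * unname(table$values[i])
  }
  total
}

# Largest interaction-form exponent over a table of the given order,
# used to draw feasible (baseline, effect) pairs in property tests.
max_exponent <- function(name, order) {
  switch(name, additive = 2 * order,
         multiplicative = 2^order, threshold = 1)
}

# Literal enumeration of observed-scale heritability.
heritability_bruteforce <- function(table) {
  freqs <- lapply(table$mafs, function(q) c((1 - q)^2, 2 * q * (1 - q), q^2))
  pi <- prevalence_bruteforce(table)
  num <- 0
  for (i in seq_len(nrow(table$tuples))) {
    w <- 1
    for (l in seq_len(table$order)) {
      w <- w * freqs[[l]][table$tuples[i, l] + 1]
    }
    num <- num + w * (unname(table$values[i]) - pi)^2
  }
  num / (pi * (1 - pi))
}

# A two-locus exclusive-or table with exactly zero marginal effects:
# penetrance is `hi` when exactly one locus carries a minor allele. With
# MAF 1 - sqrt(1/2) each locus triggers with probability 1/2, so both
# per-locus marginal penetrances collapse to (hi + lo) / 2 and cases are
# driven purely by the interaction.
xor_table <- function(hi = 0.9, lo = 0.1) {
  q <- 1 - sqrt(0.5)
  vals <- matrix(lo, 3, 3)
  for (g1 in 0:2) for (g2 in 0:2) {
    if ((g1 > 0) != (g2 > 0)) vals[g1 + 1, g2 + 1] <- hi
  }
  penetrance_table(2L, c(q, q), as.vector(t(vals)))
}

# Small balanced dataset generator used by several model tests.
tiny_epistatic_dataset <- function(form = "threshold", n = 2000L,
                                   total_snps = 20L, seed = 1L,
                                   table = NULL) {
  tab <- if (is.null(table)) solve_penetrance(form, c(0.25, 0.25), 0.25)
         else table
  model <- mixed_phenotype_model(0, sample_linear_model(0, seed = 0L), tab,
                                 integer(0), 1:2)
  balanced_dataset(model, n, total_snps, seed = seed)
}
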