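# Synthetic cohort generation: Hardy-Weinberg genotypes, the mixed
# linear + epistatic disease-probability model, balanced case-control
# sampling, alpha sweeps, GAMETES-style replicate designs, and the
# theoretical AUC of the generative model.
#
# All randomness flows from a single integer seed; every operation that
# draws random numbers takes `seed` and derives independent sub-streams
# from it (see `derive_seed`), so whole experiments replay exactly.

# Deterministic sub-stream seed: hash a root seed with a stream label.
# Keeps derived seeds within the 32-bit integer range.
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(label) * (31 ^ (seq_along(utf8ToInt(label)) %% 8)))
  as.integer((as.numeric(seed) * 2654435761 + h) %% .Machine$integer.max)
}

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

#' Sample a genotype matrix under Hardy-Weinberg equilibrium
#'
#' Each entry is the minor-allele count (0/1/2) of one individual at one
#' SNP, drawn independently with the per-SNP Hardy-Weinberg genotype
#' frequencies. SNPs are independent (no linkage disequilibrium).
#'
#' @param n Number of individuals.
#' @param snp_mafs Per-SNP minor-allele frequencies in \code{[0, 0.5]};
#'   length gives the number of SNPs.
#' @param seed Optional integer seed (reproducible draws).
#' @param snp_ids Column identifiers (default \code{snp0001, ...}).
#' @return Integer matrix \code{n x length(snp_mafs)} with entries in
#'   \{0, 1, 2\} and \code{snp_ids} as column names.
#' @export
sample_genotypes <- function(n, snp_mafs, seed = NULL, snp_ids = NULL) {
  stopifnot(n >= 1)
  if (any(snp_mafs < 0 | snp_mafs > 0.5 | is.na(snp_mafs))) {
    stop("all `snp_mafs` must be in [0, 0.5]", call. = FALSE)
  }
  S <- length(snp_mafs)
  if (is.null(snp_ids)) snp_ids <- sprintf("snp%04d", seq_len(S))
  stopifnot(length(snp_ids) == S)
  g <- with_seed(seed, {
    u <- matrix(stats::runif(n * S), n, S)
    # cumulative HWE thresholds per SNP, recycled down columns
    c0 <- matrix((1 - snp_mafs)^2, n, S, byrow = TRUE)
    c1 <- matrix((1 - snp_mafs)^2 + 2 * snp_mafs * (1 - snp_mafs), n, S,
                 byrow = TRUE)
    (u > c0) + (u > c1)
  })
  storage.mode(g) <- "integer"
  colnames(g) <- snp_ids
  g
}

#' Sample the coefficients of the logistic linear-effect model
#'
#' Intercept and per-SNP coefficients drawn i.i.d. from a zero-mean normal
#' distribution with standard deviation \code{coefficient_sd} (default 0.5).
#'
#' @param k Number of linear-effect SNPs (>= 0).
#' @param coefficient_sd Standard deviation of the coefficient
#'   distribution.
#' @param seed Optional integer seed.
#' @param intercept Optional fixed intercept; by default the intercept is
#'   sampled from the same distribution as the coefficients.
#' @return An object of class \code{"linear_effect_model"} with fields
#'   \code{intercept}, \code{coefficients}, \code{coefficient_sd}.
#' @export
sample_linear_model <- function(k, coefficient_sd = 0.5, seed = NULL,
                                intercept = NULL) {
  stopifnot(k >= 0, coefficient_sd >= 0)
  draws <- with_seed(seed, stats::rnorm(k + 1L, 0, coefficient_sd))
  if (is.null(intercept)) intercept <- draws[1L]
  structure(list(intercept = intercept,
                 coefficients = if (k > 0) draws[-1L] else numeric(0),
                 coefficient_sd = coefficient_sd),
            class = "linear_effect_model")
}

#' Logistic disease probability of the linear model
#'
#' \code{P(Y=1|x) = plogis(b0 + sum_i b_i x_i)}, numerically stable for
#' large logits.
#'
#' @param model A \code{\link{sample_linear_model}} object.
#' @param genotypes Numeric vector over the linear-effect SNPs, or a matrix
#'   with one row per individual.
#' @return Probability vector.
#' @export
linear_prob <- function(model, genotypes) {
  stopifnot(inherits(model, "linear_effect_model"))
  if (is.null(dim(genotypes))) genotypes <- matrix(genotypes, nrow = 1L)
  if (ncol(genotypes) != length(model$coefficients)) {
    stop("genotype row length ", ncol(genotypes), " does not match ",
         length(model$coefficients), " coefficients", call. = FALSE)
  }
  eta <- model$intercept +
    if (length(model$coefficients)) drop(genotypes %*% model$coefficients) else 0
  stats::plogis(eta)
}

#' The mixed linear + epistatic phenotype model
#'
#' Disease probability is a convex combination of a logistic polygenic
#' component over the linear-effect SNPs and a penetrance-table lookup over
#' the epistatic SNPs:
#' \code{P = alpha * P_linear + (1 - alpha) * P_epistatic}.
#'
#' @param alpha Mixing weight in \code{[0, 1]}; 1 = purely linear,
#'   0 = purely epistatic.
#' @param linear A \code{\link{sample_linear_model}} (may have 0
#'   coefficients when \code{alpha = 0}).
#' @param table A \code{\link{penetrance_table}}.
#' @param linear_columns Column indices of the linear-effect SNPs.
#' @param epistatic_columns Column indices of the epistatic SNPs (length
#'   must equal the table order; disjoint from \code{linear_columns}).
#' @return An object of class \code{"mixed_phenotype_model"}.
#' @export
mixed_phenotype_model <- function(alpha, linear, table, linear_columns,
                                  epistatic_columns) {
  stopifnot(inherits(linear, "linear_effect_model"),
            inherits(table, "penetrance_table"))
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0 || alpha > 1) {
    stop("`alpha` must be a single value in [0, 1]", call. = FALSE)
  }
  if (length(epistatic_columns) != table$order) {
    stop("`epistatic_columns` must have length ", table$order, call. = FALSE)
  }
  if (length(linear_columns) != length(linear$coefficients)) {
    stop("`linear_columns` must match the number of linear coefficients",
         call. = FALSE)
  }
  if (length(intersect(linear_columns, epistatic_columns))) {
    stop("linear and epistatic column sets must be disjoint", call. = FALSE)
  }
  structure(list(alpha = alpha, linear = linear, table = table,
                 linear_columns = as.integer(linear_columns),
                 epistatic_columns = as.integer(epistatic_columns)),
            class = "mixed_phenotype_model")
}

# Lexicographic linear index of epistatic genotype tuples into the table.
tuple_index <- function(g_epi, order) {
  idx <- rep(1, nrow(g_epi))
  for (l in seq_len(order)) idx <- idx + g_epi[, l] * 3^(order - l)
  idx
}

#' Disease probability under the mixed model
#'
#' @param model A \code{\link{mixed_phenotype_model}}.
#' @param genotypes Genotype row (vector over all SNP columns the model
#'   indexes into) or matrix with one row per individual.
#' @return Probability vector in \code{[0, 1]}.
#' @export
mixed_prob <- function(model, genotypes) {
  stopifnot(inherits(model, "mixed_phenotype_model"))
  if (is.null(dim(genotypes))) genotypes <- matrix(genotypes, nrow = 1L)
  g_epi <- genotypes[, model$epistatic_columns, drop = FALSE]
  if (any(g_epi != floor(g_epi)) || any(g_epi < 0) || any(g_epi > 2)) {
    stop("epistatic genotypes outside {0,1,2}: no matching table entry",
         call. = FALSE)
  }
  p_epi <- model$table$values[tuple_index(g_epi, model$table$order)]
  p_lin <- if (model$alpha > 0) {
    linear_prob(model$linear,
                genotypes[, model$linear_columns, drop = FALSE])
  } else 0.5  # unused when alpha = 0
  unname(model$alpha * p_lin + (1 - model$alpha) * p_epi)
}

#' Draw binary phenotypes from per-individual disease probabilities
#'
#' @param probabilities Vector of probabilities in \code{[0, 1]}.
#' @param seed Optional integer seed.
#' @return Integer vector of labels (1 = case, 0 = control).
#' @export
assign_phenotypes <- function(probabilities, seed = NULL) {
  if (any(probabilities < 0 | probabilities > 1 | is.na(probabilities))) {
    stop("all probabilities must be in [0, 1]", call. = FALSE)
  }
  with_seed(seed,
            as.integer(stats::rbinom(length(probabilities), 1L, probabilities)))
}

new_dataset <- function(genotypes, labels, provenance) {
  stopifnot(nrow(genotypes) == length(labels), all(labels %in% c(0L, 1L)))
  structure(list(genotypes = genotypes, labels = as.integer(labels),
                 provenance = provenance),
            class = "epibench_dataset")
}

#' @export
print.epibench_dataset <- function(x, ...) {
  cat(sprintf("<epibench_dataset> %d individuals x %d SNPs, %d cases / %d controls\n",
              nrow(x$genotypes), ncol(x$genotypes),
              sum(x$labels == 1L), sum(x$labels == 0L)))
  invisible(x)
}

#' Generate a balanced case-control cohort from a mixed phenotype model
#'
#' Individuals are generated (genotype, disease probability, Bernoulli
#' label) and rejection-sampled until exactly \code{n/2} cases and
#' \code{n/2} controls are collected, emulating the balanced replicate
#' design of GAMETES-style simulators. Only the effect columns (linear +
#' epistatic) determine the label, so noise SNPs are filled in for the
#' accepted individuals only.
#'
#' @param model A \code{\link{mixed_phenotype_model}} whose column indices
#'   refer into the full SNP panel of \code{total_snps} columns.
#' @param n Cohort size (even).
#' @param total_snps Total number of SNPs (effect + noise).
#' @param snp_mafs Either a single MAF applied to the noise SNPs or a
#'   vector of length \code{total_snps}. Effect-column MAFs default to the
#'   model's own (table MAFs for epistatic columns, 0.5 for linear ones,
#'   matching the 0.25/0.5/0.25 genotype frequencies of the base design).
#' @param seed Optional integer seed.
#' @param max_batches Safety cap on rejection-sampling rounds.
#' @return An \code{epibench_dataset} with \code{n/2} cases, \code{n/2}
#'   controls and provenance recording the model and seed.
#' @export
balanced_dataset <- function(model, n, total_snps, snp_mafs = 0.5,
                             seed = NULL, max_batches = 400L) {
  stopifnot(inherits(model, "mixed_phenotype_model"), n %% 2 == 0, n >= 2)
  eff_cols <- c(model$linear_columns, model$epistatic_columns)
  if (length(eff_cols) && max(eff_cols) > total_snps) {
    stop("model columns exceed `total_snps`", call. = FALSE)
  }
  if (length(snp_mafs) == 1L) snp_mafs <- rep(snp_mafs, total_snps)
  stopifnot(length(snp_mafs) == total_snps)
  snp_mafs[model$epistatic_columns] <- model$table$mafs

  eff_mafs <- snp_mafs[eff_cols]
  need <- n / 2L
  half <- function(m) m[seq_len(min(nrow(m), need)), , drop = FALSE]
  cases <- controls <- matrix(0L, 0L, length(eff_cols))
  batch <- max(4L * n, 20000L)
  seen <- got_cases <- got_controls <- 0
  b <- 0L
  while (nrow(cases) < need || nrow(controls) < need) {
    b <- b + 1L
    if (b > max_batches) {
      stop("rejection sampling did not fill case/control quotas (acceptance ",
           "probability too low for one class)", call. = FALSE)
    }
    g <- sample_genotypes(batch, eff_mafs,
                          seed = if (is.null(seed)) NULL
                                 else derive_seed(seed, paste0("eff", b)))
    gm <- matrix(0L, nrow(g), total_snps)
    gm[, eff_cols] <- g
    p <- mixed_prob(model, gm)
    y <- assign_phenotypes(p, seed = if (is.null(seed)) NULL
                                     else derive_seed(seed, paste0("lab", b)))
    seen <- seen + length(y)
    got_cases <- got_cases + sum(y == 1L)
    got_controls <- got_controls + sum(y == 0L)
    if (nrow(cases) < need) cases <- half(rbind(cases, g[y == 1L, , drop = FALSE]))
    if (nrow(controls) < need) controls <- half(rbind(controls, g[y == 0L, , drop = FALSE]))
    if (seen >= 4L * batch) {
      rate <- min(got_cases, got_controls) / seen
      if (rate < 1e-4) {
        stop(sprintf(
          "infeasible balance: empirical acceptance probability %.2g < 1e-4 for the rarer class",
          rate), call. = FALSE)
      }
    }
  }
  eff <- rbind(cases, controls)
  labels <- rep(c(1L, 0L), each = need)
  perm <- with_seed(if (is.null(seed)) NULL else derive_seed(seed, "perm"),
                    sample.int(n))
  eff <- eff[perm, , drop = FALSE]
  labels <- labels[perm]
  genotypes <- sample_genotypes(
    n, snp_mafs, seed = if (is.null(seed)) NULL else derive_seed(seed, "noise"))
  genotypes[, eff_cols] <- eff
  new_dataset(genotypes, labels, provenance = list(
    design = "balanced_rejection", n = n, total_snps = total_snps,
    alpha = model$alpha, table_form = attr(model$table, "form")$name,
    table_mafs = model$table$mafs, linear_columns = model$linear_columns,
    epistatic_columns = model$epistatic_columns, seed = seed))
}

#' Label sweeps over one shared genotype matrix for a grid of alpha values
#'
#' Reuses a single genotype matrix and draws one phenotype vector per
#' mixing weight, producing a family of datasets that differ only in how
#' much of the disease probability is epistatic.
#'
#' @param base_genotypes Genotype matrix (from
#'   \code{\link{sample_genotypes}}).
#' @param linear A \code{\link{sample_linear_model}}.
#' @param table A \code{\link{penetrance_table}}.
#' @param alphas Vector of mixing weights in \code{[0, 1]} (default: 10
#'   evenly spaced values from 1 down to 0).
#' @param linear_columns,epistatic_columns Column index sets (defaults:
#'   first \code{k} columns linear, next \code{order} columns epistatic).
#' @param seed Optional integer seed (one label sub-stream per alpha).
#' @return Named list of \code{epibench_dataset}s (names \code{alpha=x}),
#'   all sharing \code{base_genotypes}.
#' @export
alpha_sweep <- function(base_genotypes, linear, table,
                        alphas = seq(1, 0, length.out = 10L),
                        linear_columns = seq_along(linear$coefficients),
                        epistatic_columns = length(linear$coefficients) +
                          seq_len(table$order),
                        seed = NULL) {
  stopifnot(all(alphas >= 0 & alphas <= 1))
  out <- lapply(seq_along(alphas), function(i) {
    a <- alphas[i]
    model <- mixed_phenotype_model(a, linear, table, linear_columns,
                                   epistatic_columns)
    p <- mixed_prob(model, base_genotypes)
    y <- assign_phenotypes(p, seed = if (is.null(seed)) NULL
                                     else derive_seed(seed, paste0("alpha", i)))
    new_dataset(base_genotypes, y, provenance = list(
      design = "alpha_sweep", alpha = a, table_form = attr(table, "form")$name,
      linear_columns = linear_columns, epistatic_columns = epistatic_columns,
      seed = seed))
  })
  names(out) <- paste0("alpha=", format(alphas))
  out
}

#' GAMETES-style replicate experiment: pure 2-locus epistasis cohorts
#'
#' Solves one penetrance table per interaction form, then generates
#' independent balanced replicates at \code{alpha = 0} (purely epistatic
#' phenotype) with the causal loci embedded in a panel of noise SNPs.
#'
#' @param form_name Interaction form (\code{"additive"},
#'   \code{"multiplicative"}, \code{"threshold"}).
#' @param target_h2 Target heritability (default 0.25).
#' @param mafs Causal-locus MAFs (default \code{c(0.25, 0.25)}).
#' @param replicates Number of replicate datasets (default 10).
#' @param n Cohort size per replicate (default 20000).
#' @param total_snps SNP panel size (default 1000; causal loci at columns
#'   1..order by default).
#' @param noise_maf MAF of the non-causal SNPs (default 0.5, i.e. genotype
#'   frequencies 0.25/0.5/0.25).
#' @param seed Optional integer seed.
#' @return List with \code{table} (the solved \code{penetrance_table}) and
#'   \code{datasets} (list of \code{replicates} balanced datasets).
#' @export
gametes_experiment <- function(form_name, target_h2 = 0.25,
                               mafs = c(0.25, 0.25), replicates = 10L,
                               n = 20000L, total_snps = 1000L,
                               noise_maf = 0.5, seed = NULL) {
  stopifnot(replicates >= 1L)
  tab <- solve_penetrance(form_name, mafs, target_h2)
  order <- tab$order
  model <- mixed_phenotype_model(
    alpha = 0, linear = sample_linear_model(0, seed = 0L), table = tab,
    linear_columns = integer(0), epistatic_columns = seq_len(order))
  datasets <- lapply(seq_len(replicates), function(r) {
    ds <- balanced_dataset(model, n, total_snps, snp_mafs = noise_maf,
                           seed = if (is.null(seed)) NULL
                                  else derive_seed(seed, paste0("rep", r)))
    ds$provenance$replicate <- r
    ds$provenance$form <- form_name
    ds$provenance$target_h2 <- target_h2
    ds
  })
  list(table = tab, datasets = datasets)
}

#' Theoretical AUC-ROC of the generative disease model
#'
#' The AUC attained when the ground-truth disease probability itself is
#' used as the classification score: the performance ceiling for any
#' trained classifier on data drawn from the model. With score classes
#' \code{s_g} occurring with probability \code{P(g)} and labels
#' \code{Y ~ Bernoulli(s_g)},
#' \deqn{AUC = \frac{\sum_{i,j} P_i P_j s_i (1 - s_j)
#'   [1(s_i > s_j) + 0.5 \cdot 1(s_i = s_j)]}{\pi (1 - \pi)},
#'   \quad \pi = \sum_g P_g s_g.}
#'
#' @param model A \code{\link{mixed_phenotype_model}}.
#' @param method \code{"exact"} (enumerates all genotype combinations of
#'   the effect SNPs; requires at most \code{1e6} score classes) or
#'   \code{"monte_carlo"}.
#' @param mc_draws Number of Monte-Carlo draws (default \code{1e6}).
#' @param seed Optional integer seed (Monte-Carlo only).
#' @return AUC value in \code{[0.5, 1]} (up to Monte-Carlo noise).
#' @export
theoretical_auc <- function(model, method = c("exact", "monte_carlo"),
                            mc_draws = 1e6, seed = NULL) {
  stopifnot(inherits(model, "mixed_phenotype_model"))
  method <- match.arg(method)
  k <- length(model$linear_columns)
  L <- model$table$order
  if (method == "exact") {
    n_classes <- 3^(k * (model$alpha > 0) + L)
    if (n_classes > 1e6) {
      stop("exact enumeration needs ", n_classes, " > 1e6 score classes; ",
           "use method = \"monte_carlo\"", call. = FALSE)
    }
    # enumerate effect genotypes with their HWE probabilities
    if (model$alpha > 0 && k > 0) {
      cols <- c(model$linear_columns, model$epistatic_columns)
      grids <- rep(list(0:2), k + L)
      combos <- as.matrix(expand.grid(grids))
      gm <- matrix(0L, nrow(combos), max(cols))
      gm[, cols] <- combos
      # per-column HWE weights: linear SNPs at MAF 0.5 design frequencies
      w <- rep(1, nrow(combos))
      mafs <- c(rep(0.5, k), model$table$mafs)
      for (j in seq_len(k + L)) {
        f <- hwe_genotype_freqs(mafs[j])
        w <- w * f[combos[, j] + 1L]
      }
      s <- mixed_prob(model, gm)
    } else {
      # no linear SNPs contribute: score classes are the table cells
      # (plus a constant plogis(b0) term when alpha > 0)
      w <- tuple_weights(model$table)
      p_lin <- if (model$alpha > 0) stats::plogis(model$linear$intercept)
               else 0
      s <- unname(model$alpha * p_lin +
                    (1 - model$alpha) * model$table$values)
    }
    # collapse duplicate scores for the O(m^2) pair sum
    agg <- rowsum(w, group = signif(s, 14))
    sv <- as.numeric(rownames(agg))
    wv <- as.numeric(agg)
    o <- order(sv)
    sv <- sv[o]; wv <- wv[o]
    pi <- sum(wv * sv)
    if (pi <= 0 || pi >= 1) return(0.5)
    # sum over ordered pairs: each score class i contributes its case mass
    # against the control mass of all strictly lower classes, ties half
    ctrl_below <- c(0, cumsum(wv * (1 - sv))[-length(wv)])
    num <- sum(wv * sv * ctrl_below) + 0.5 * sum(wv^2 * sv * (1 - sv))
    num / (pi * (1 - pi))
  } else {
    with_seed(seed, {
      cols <- c(model$linear_columns, model$epistatic_columns)
      mafs <- c(rep(0.5, k), model$table$mafs)
      g <- sample_genotypes(mc_draws, mafs)
      gm <- matrix(0L, mc_draws, if (length(cols)) max(cols) else L)
      gm[, if (length(cols)) cols else seq_len(L)] <- g
      s <- mixed_prob(model, gm)
      y <- stats::rbinom(mc_draws, 1L, s)
      auc_rank(y, s)
    })
  }
}

# Mann-Whitney rank AUC with half credit for ties (shared with evaluate).
auc_rank <- function(labels, scores) {
  n1 <- as.numeric(sum(labels == 1L))
  n0 <- as.numeric(sum(labels == 0L))
  if (n1 == 0L || n0 == 0L) {
    stop("AUC undefined: both classes must be present", call. = FALSE)
  }
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Write / read a dataset in GAMETES-style tab-delimited text
#'
#' One header row with SNP identifiers and a final \code{Class} column;
#' genotype cells 0/1/2; class 0/1. Provenance is written alongside as a
#' human-readable key-value sidecar \code{<path>.provenance}.
#'
#' @param dataset An \code{epibench_dataset}.
#' @param path Output TSV path.
#' @return \code{path}, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "epibench_dataset"))
  df <- as.data.frame(dataset$genotypes)
  df$Class <- dataset$labels
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  prov <- dataset$provenance
  if (length(prov)) {
    lines <- vapply(names(prov), function(k) {
      paste0(k, " = ", paste(format(prov[[k]]), collapse = ","))
    }, character(1))
    writeLines(lines, paste0(path, ".provenance"))
  }
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  if (!"Class" %in% colnames(df)) {
    stop("dataset file lacks a 'Class' column: ", path, call. = FALSE)
  }
  labels <- as.integer(df$Class)
  g <- as.matrix(df[, setdiff(colnames(df), "Class"), drop = FALSE])
  storage.mode(g) <- "integer"
  if (any(!g %in% c(0L, 1L, 2L))) {
    stop("genotype entries outside {0,1,2} in ", path, call. = FALSE)
  }
  prov <- list(source = path)
  side <- paste0(path, ".provenance")
  if (file.exists(side)) {
    kv <- strsplit(readLines(side), " = ", fixed = TRUE)
    prov <- c(prov, stats::setNames(lapply(kv, `[`, 2L),
                                    vapply(kv, `[`, character(1), 1L)))
  }
  new_dataset(g, labels, prov)
}
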