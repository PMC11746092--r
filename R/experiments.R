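# Experiment drivers reproducing the two simulation studies: the
# balanced GAMETES-style replicate benchmark across interaction forms,
# and the alpha sweep trading the linear against the epistatic component
# over one shared genotype matrix.

#' Experiment configuration
#'
#' Validated bundle of the design knobs shared by the drivers. Counts
#' must be positive, the alpha grid within \code{[0, 1]}, and the root
#' seed is recorded in every output artifact.
#'
#' @param design \code{"gametes_table"} or \code{"alpha_sweep"}.
#' @param n Cohort size.
#' @param total_snps SNP panel size.
#' @param n_linear Number of linear-effect SNPs (alpha sweep).
#' @param forms Interaction forms to run.
#' @param target_h2 Heritability target.
#' @param mafs Causal-locus MAFs.
#' @param alphas Alpha grid (alpha sweep).
#' @param families Model families to benchmark.
#' @param cycles Holdout cycles per dataset.
#' @param replicates Replicate datasets per form (benchmark).
#' @param seed Root seed.
#' @param coefficient_sd Linear coefficient scale (default 0.5).
#' @param output_dir Optional directory for TSV artifacts.
#' @return A list of class \code{"experiment_config"}.
#' @export
experiment_config <- function(design = c("gametes_table", "alpha_sweep"),
                              n = 20000L, total_snps = 1000L,
                              n_linear = 25L,
                              forms = c("additive", "multiplicative",
                                        "threshold"),
                              target_h2 = 0.25, mafs = c(0.25, 0.25),
                              alphas = seq(1, 0, length.out = 10L),
                              families = c("lasso_logistic",
                                           "gradient_boosting"),
                              cycles = 5L, replicates = 10L, seed = 1L,
                              coefficient_sd = 0.5, output_dir = NULL) {
  design <- match.arg(design)
  stopifnot(n > 0, total_snps > 0, n_linear >= 0, cycles > 0,
            replicates > 0, all(alphas >= 0 & alphas <= 1))
  if (!length(families)) stop("`families` must be non-empty", call. = FALSE)
  families <- vapply(families, match.arg, character(1),
                     choices = classifier_families)
  forms <- vapply(forms, match.arg, character(1),
                  choices = c("additive", "multiplicative", "threshold"))
  structure(list(design = design, n = as.integer(n),
                 total_snps = as.integer(total_snps),
                 n_linear = as.integer(n_linear), forms = unname(forms),
                 target_h2 = target_h2, mafs = mafs, alphas = alphas,
                 families = unname(families), cycles = as.integer(cycles),
                 replicates = as.integer(replicates),
                 seed = as.integer(seed), coefficient_sd = coefficient_sd,
                 output_dir = output_dir),
            class = "experiment_config")
}

default_spec <- function(family, protocol = training_protocol()) {
  classifier_spec(family, protocol = protocol)
}

#' Run the balanced replicate benchmark across interaction forms
#'
#' For every form: solve the penetrance table at the configured
#' heritability, generate \code{replicates} balanced cohorts of pure
#' epistasis (alpha = 0), evaluate every requested family with the
#' repeated holdout protocol, and aggregate into a benchmark table
#' (mean +/- sd across replicates).
#'
#' @param config An \code{\link{experiment_config}}.
#' @param specs Optional named list of \code{\link{classifier_spec}}s to
#'   override the per-family defaults.
#' @return List with \code{summaries} (per form: \code{replicate_summary}
#'   output), \code{reports} (nested per form/family/replicate),
#'   \code{tables} (solved penetrance tables), \code{config}.
#' @export
run_gametes_benchmark <- function(config, specs = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  out <- list(summaries = list(), reports = list(), tables = list(),
              config = config)
  for (form in config$forms) {
    exp <- gametes_experiment(
      form, target_h2 = config$target_h2, mafs = config$mafs,
      replicates = config$replicates, n = config$n,
      total_snps = config$total_snps,
      seed = derive_seed(config$seed, paste0("gametes_", form)))
    out$tables[[form]] <- exp$table
    features <- lapply(exp$datasets, function(d) one_hot_encode(d$genotypes))
    reports <- list()
    for (family in config$families) {
      spec <- if (!is.null(specs[[family]])) specs[[family]]
              else default_spec(family)
      fam_reports <- lapply(seq_along(exp$datasets), function(r) {
        cross_validate(spec, exp$datasets[[r]], cycles = config$cycles,
                       seed = derive_seed(config$seed,
                                          paste0(form, "_", family, "_", r)),
                       features = features[[r]])
      })
      reports[[family]] <- fam_reports
    }
    out$reports[[form]] <- reports
    out$summaries[[form]] <- replicate_summary(unlist(reports,
                                                      recursive = FALSE))
    if (!is.null(config$output_dir)) {
      dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
      utils::write.table(
        out$summaries[[form]]$long,
        file.path(config$output_dir, paste0("benchmark_", form, ".tsv")),
        sep = "\t", quote = FALSE, row.names = FALSE)
      write_penetrance_table(
        exp$table, file.path(config$output_dir, paste0("table_", form, ".txt")))
    }
  }
  if (!is.null(config$output_dir)) {
    writeLines(c(paste0("seed = ", config$seed),
                 paste0("config_hash = ", config_hash(config))),
               file.path(config$output_dir, "run_info.txt"))
  }
  out
}

#' Run the alpha sweep: linear-to-epistatic phenotype gradient
#'
#' Generates one genotype matrix, sweeps the mixing weight alpha over the
#' configured grid (one phenotype vector per alpha on the shared
#' genotypes), evaluates every family at every alpha, and computes the
#' theoretical AUC of the generative model per alpha. The default
#' epistatic component is a three-locus threshold table: its
#' max-prevalence solution sits near prevalence 0.5, which keeps every
#' label vector of the sweep close to class balance without rejection
#' sampling.
#'
#' @param config An \code{\link{experiment_config}} with
#'   \code{design = "alpha_sweep"}.
#' @param specs Optional named list of per-family
#'   \code{\link{classifier_spec}} overrides.
#' @param form Interaction form of the epistatic component (default
#'   \code{"threshold"}).
#' @param order Number of epistatic loci (default 3, the sweep design).
#' @return List with \code{results} (long data frame: alpha, family,
#'   metric, mean, ci_low, ci_high), \code{theoretical} (data frame
#'   alpha, theoretical_auc), \code{datasets}, \code{config}.
#' @export
run_alpha_sweep <- function(config, specs = NULL, form = "threshold",
                            order = 3L) {
  stopifnot(inherits(config, "experiment_config"))
  if (!length(config$families)) stop("`families` must be non-empty",
                                     call. = FALSE)
  mafs <- if (length(config$mafs) == order) config$mafs
          else rep(config$mafs[1L], order)
  tab <- solve_penetrance(form, mafs, config$target_h2)
  k <- config$n_linear
  lin <- sample_linear_model(k, config$coefficient_sd,
                             seed = derive_seed(config$seed, "beta"))
  genotypes <- sample_genotypes(
    config$n, c(rep(0.5, k), tab$mafs,
                rep(0.5, config$total_snps - k - order)),
    seed = derive_seed(config$seed, "genotypes"))
  lin_cols <- seq_len(k)
  epi_cols <- k + seq_len(order)
  datasets <- alpha_sweep(genotypes, lin, tab, alphas = config$alphas,
                          linear_columns = lin_cols,
                          epistatic_columns = epi_cols,
                          seed = derive_seed(config$seed, "sweep"))
  features <- one_hot_encode(genotypes)
  theo <- data.frame(alpha = config$alphas, theoretical_auc = NA_real_)
  results <- NULL
  for (i in seq_along(config$alphas)) {
    a <- config$alphas[i]
    model <- mixed_phenotype_model(a, lin, tab, lin_cols, epi_cols)
    n_classes <- 3^(k * (a > 0) + order)
    theo$theoretical_auc[i] <- theoretical_auc(
      model, method = if (n_classes <= 1e6) "exact" else "monte_carlo",
      mc_draws = 2e5, seed = derive_seed(config$seed, paste0("mc", i)))
    for (family in config$families) {
      spec <- if (!is.null(specs[[family]])) specs[[family]]
              else default_spec(family)
      rep_seed <- derive_seed(config$seed, paste0("cv_", family, "_", i))
      report <- cross_validate(spec, datasets[[i]], cycles = config$cycles,
                               seed = rep_seed, features = features)
      agg <- report$aggregate
      results <- rbind(results, data.frame(
        alpha = a, family = family, metric = agg$metric, mean = agg$mean,
        ci_low = agg$ci_low, ci_high = agg$ci_high))
    }
  }
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(results,
                       file.path(config$output_dir, "alpha_sweep.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(theo,
                       file.path(config$output_dir, "theoretical_auc.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(c(paste0("seed = ", config$seed),
                 paste0("config_hash = ", config_hash(config))),
               file.path(config$output_dir, "run_info.txt"))
  }
  list(results = results, theoretical = theo, datasets = datasets,
       config = config)
}

# Stable short hash of a configuration (embedded in artifacts).
config_hash <- function(config) {
  s <- paste(deparse(config[setdiff(names(config), "output_dir")]),
             collapse = "")
  v <- utf8ToInt(s)
  format(sum(v * (seq_along(v) %% 97 + 1)) %% 1e9)
}
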