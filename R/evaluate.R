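# Metrics and the repeated stratified holdout protocol.
#
# "Cross-validation" here is repeated random splitting (5 cycles of
# stratified 60:40 train/test by default), not k-fold; neural families
# split the 40% holdout equally into a validation half (hyperparameter
# selection, early stopping, checkpointing) and an independent test half.

#' Binary classification metrics
#'
#' Accuracy, precision, recall and F1 at a probability threshold
#' (default 0.5); AUC-ROC as the Mann-Whitney rank statistic with half
#' credit for ties; AUC-PR by step-wise integration of the
#' precision-recall curve (no interpolation). Precision (and hence F1) is
#' defined as 0 when no sample is predicted positive.
#'
#' @param labels 0/1 vector.
#' @param scores Predicted case probabilities (same length).
#' @param threshold Classification threshold (default 0.5).
#' @return Named numeric vector with elements \code{accuracy},
#'   \code{auc_roc}, \code{auc_pr}, \code{precision}, \code{recall},
#'   \code{f1}.
#' @export
binary_metrics <- function(labels, scores, threshold = 0.5) {
  if (length(labels) == 0L) stop("empty input", call. = FALSE)
  if (length(labels) != length(scores)) {
    stop("labels and scores must have equal length", call. = FALSE)
  }
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) {
    stop("AUC undefined: both classes must be present", call. = FALSE)
  }
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1L & labels == 1L)
  fp <- sum(pred == 1L & labels == 0L)
  fn <- sum(pred == 0L & labels == 1L)
  tn <- sum(pred == 0L & labels == 0L)
  accuracy <- (tp + tn) / length(labels)
  precision <- if (tp + fp == 0L) 0 else tp / (tp + fp)
  recall <- tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  c(accuracy = accuracy, auc_roc = auc_rank(labels, scores),
    auc_pr = auc_pr(labels, scores), precision = precision,
    recall = recall, f1 = f1)
}

# Step-wise precision-recall integral: process scores in descending
# order, grouping tied scores; area = sum over recall increments of the
# precision after including each group.
auc_pr <- function(labels, scores) {
  o <- order(scores, decreasing = TRUE)
  y <- as.integer(labels)[o]
  s <- scores[o]
  grp_last <- c(which(diff(s) != 0), length(s))  # last index of each tie group
  tp <- cumsum(y)[grp_last]
  pos <- grp_last
  n1 <- sum(y)
  prec <- tp / pos
  rec <- tp / n1
  sum(diff(c(0, rec)) * prec)
}

stratified_split <- function(labels, fractions) {
  # fractions: named numeric summing to 1, e.g. c(train=.6, test=.4)
  parts <- lapply(names(fractions), function(nm) integer(0))
  names(parts) <- names(fractions)
  for (cls in unique(labels)) {
    idx <- sample(which(labels == cls))
    n <- length(idx)
    sizes <- floor(fractions * n)
    sizes[1L] <- n - sum(sizes[-1L])
    start <- 1L
    for (p in names(fractions)) {
      parts[[p]] <- c(parts[[p]], idx[seq.int(start, length.out = sizes[[p]])])
      start <- start + sizes[[p]]
    }
  }
  parts
}

#' Repeated stratified holdout evaluation of one classifier family
#'
#' Per cycle: a fresh stratified split into 60\% training and 40\%
#' holdout. Non-neural families are fitted on the training portion
#' (hyperparameters resolved internally, e.g. the lasso penalty by
#' cross-validation on the training set) and scored on the full holdout.
#' Neural families split the holdout equally into validation and
#' independent test halves, run \code{\link{grid_search}} selecting by
#' validation AUC-ROC, and are scored on the independent test half only.
#' The aggregate is the per-metric mean, standard deviation and normal
#' 95\% confidence interval (mean +/- 1.96 sd / sqrt(cycles)).
#'
#' @param spec A \code{\link{classifier_spec}}.
#' @param dataset An \code{epibench_dataset} (or a list with
#'   \code{genotypes} and \code{labels}).
#' @param cycles Number of split cycles (default 5).
#' @param train_frac Training fraction (default 0.6).
#' @param seed Optional integer seed.
#' @param features Optional pre-computed one-hot matrix (to share the
#'   encoding across several calls on the same dataset).
#' @return A \code{metrics_report}: list with \code{per_cycle} (data
#'   frame), \code{aggregate} (metric, mean, sd, ci_low, ci_high),
#'   \code{metadata}.
#' @export
cross_validate <- function(spec, dataset, cycles = 5L, train_frac = 0.6,
                           seed = NULL, features = NULL) {
  stopifnot(inherits(spec, "classifier_spec"), cycles >= 1L,
            train_frac > 0, train_frac < 1)
  y <- dataset$labels
  if (length(unique(y)) < 2L) stop("dataset must contain both classes",
                                   call. = FALSE)
  X <- if (is.null(features)) one_hot_encode(dataset$genotypes) else features
  neural <- is_neural_family(spec$family)
  per_cycle <- NULL
  for (cy in seq_len(cycles)) {
    cy_seed <- if (is.null(seed)) NULL else derive_seed(seed, paste0("cycle", cy))
    split <- with_seed(cy_seed, {
      if (neural) {
        stratified_split(y, c(train = train_frac,
                              val = (1 - train_frac) / 2,
                              test = (1 - train_frac) / 2))
      } else {
        stratified_split(y, c(train = train_frac, test = 1 - train_frac))
      }
    })
    if (neural) {
      gs <- grid_search(spec$family, spec$grid,
                        X[split$train, , drop = FALSE], y[split$train],
                        X[split$val, , drop = FALSE], y[split$val],
                        protocol = spec$protocol, seed = cy_seed,
                        strict = spec$strict)
      fitted <- gs$best
    } else {
      hp <- lapply(spec$grid, function(v) if (length(v) == 1L) v[[1L]] else unlist(v))
      clf <- build_classifier(spec$family, hp, n_features = ncol(X),
                              protocol = spec$protocol, strict = spec$strict)
      fitted <- fit_classifier(clf, X[split$train, , drop = FALSE],
                               y[split$train], seed = cy_seed)
    }
    p <- predict_proba(fitted, X[split$test, , drop = FALSE])
    m <- binary_metrics(y[split$test], p)
    per_cycle <- rbind(per_cycle,
                       data.frame(cycle = cy, t(m), row.names = NULL))
  }
  metric_names <- setdiff(colnames(per_cycle), "cycle")
  agg <- do.call(rbind, lapply(metric_names, function(mn) {
    v <- per_cycle[[mn]]
    mu <- mean(v); sdv <- stats::sd(v)
    if (cycles == 1L) sdv <- NA_real_
    half <- 1.96 * sdv / sqrt(cycles)
    data.frame(metric = mn, mean = mu, sd = sdv,
               ci_low = mu - half, ci_high = mu + half)
  }))
  structure(list(per_cycle = per_cycle, aggregate = agg,
                 metadata = list(family = spec$family, cycles = cycles,
                                 train_frac = train_frac, seed = seed,
                                 provenance = dataset$provenance)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> %s, %d cycles\n", x$metadata$family,
              x$metadata$cycles))
  print(transform(x$aggregate, mean = round(mean, 4), sd = round(sd, 4),
                  ci_low = round(ci_low, 4), ci_high = round(ci_high, 4)),
        row.names = FALSE)
  invisible(x)
}

#' Summarise metric reports across replicate datasets
#'
#' Produces the benchmark-table shape: one row per model family, one
#' mean +/- sd cell per metric, aggregated over the replicate-level
#' report means.
#'
#' @param reports List of \code{metrics_report}s (several families, each
#'   over one or more replicate datasets).
#' @return List with \code{long} (data frame family, metric, mean, sd,
#'   n_replicates) and \code{table} (formatted wide data frame).
#' @export
replicate_summary <- function(reports) {
  stopifnot(length(reports) >= 1L)
  metric_sets <- lapply(reports, function(r) sort(r$aggregate$metric))
  if (length(unique(vapply(metric_sets, paste, character(1), collapse = ","))) != 1L) {
    stop("reports carry inconsistent metric sets", call. = FALSE)
  }
  rows <- do.call(rbind, lapply(reports, function(r) {
    data.frame(family = r$metadata$family, metric = r$aggregate$metric,
               value = r$aggregate$mean)
  }))
  long <- do.call(rbind, lapply(split(rows, list(rows$family, rows$metric),
                                      drop = TRUE), function(d) {
    data.frame(family = d$family[1L], metric = d$metric[1L],
               mean = mean(d$value),
               sd = if (nrow(d) > 1L) stats::sd(d$value) else NA_real_,
               n_replicates = nrow(d))
  }))
  rownames(long) <- NULL
  fams <- unique(long$family)
  mets <- unique(long$metric)
  wide <- data.frame(family = fams)
  for (mn in mets) {
    wide[[mn]] <- vapply(fams, function(f) {
      r <- long[long$family == f & long$metric == mn, ]
      if (is.na(r$sd)) sprintf("%.3f (single run)", r$mean)
      else sprintf("%.3f ± %.3f", r$mean, r$sd)
    }, character(1))
  }
  list(long = long, table = wide)
}

#' Write a metrics report to disk
#'
#' Writes the per-cycle and aggregate tables as TSV and a structured JSON
#' mirror of the whole report.
#'
#' @param report A \code{metrics_report}.
#' @param stem Output path stem; creates \code{<stem>_cycles.tsv},
#'   \code{<stem>_aggregate.tsv}, \code{<stem>.json}.
#' @return The stem, invisibly.
#' @export
write_metrics_report <- function(report, stem) {
  utils::write.table(report$per_cycle, paste0(stem, "_cycles.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report$aggregate, paste0(stem, "_aggregate.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(per_cycle = report$per_cycle,
                            aggregate = report$aggregate,
                            metadata = report$metadata),
                       paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null", force = TRUE)
  invisible(stem)
}
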