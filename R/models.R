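# The model zoo: seven classifier families behind one train/predict
# contract. Linear and tree families delegate to glmnet, ranger and
# xgboost; the neural families run on the package's own engine (nn.R).

#' One-hot encode a genotype matrix
#'
#' Expands each SNP into three indicator columns (genotype 0/1/2), ordered
#' lexicographically by (SNP, genotype level); exactly one indicator per
#' SNP is set in every row. Returned as a sparse \code{dgCMatrix} (each
#' row has \code{n_snps} ones out of \code{3 n_snps} columns).
#'
#' @param genotypes Integer matrix with entries in \{0, 1, 2\}.
#' @return Sparse matrix \code{n x 3*n_snps} with column names
#'   \code{<snp>_<level>}.
#' @export
one_hot_encode <- function(genotypes) {
  if (is.null(dim(genotypes))) genotypes <- matrix(genotypes, nrow = 1L)
  bad <- which(!(genotypes %in% c(0L, 1L, 2L)))
  if (length(bad)) {
    i <- arrayInd(bad[1L], dim(genotypes))
    stop(sprintf("genotype entry not in {0,1,2} at row %d, column %d: %s",
                 i[1L], i[2L], format(genotypes[bad[1L]])), call. = FALSE)
  }
  n <- nrow(genotypes); S <- ncol(genotypes)
  j <- (rep.int(seq_len(S) - 1L, rep.int(n, S))) * 3L +
    as.integer(genotypes) + 1L
  ids <- colnames(genotypes)
  if (is.null(ids)) ids <- sprintf("snp%04d", seq_len(S))
  Matrix::sparseMatrix(
    i = rep.int(seq_len(n), S), j = j, x = 1, dims = c(n, 3L * S),
    dimnames = list(NULL, paste0(rep(ids, each = 3L), "_", 0:2)))
}

classifier_families <- c("lasso_logistic", "random_forest",
                         "gradient_boosting", "mlp", "cnn", "rnn", "rnn_cnn")

neural_families <- c("mlp", "cnn", "rnn", "rnn_cnn")

#' Is a classifier family a neural network?
#'
#' Neural families receive the extra validation/test split and the epoch
#' training protocol; the linear and tree families do not.
#'
#' @param family Family name.
#' @return Logical.
#' @export
is_neural_family <- function(family) family %in% neural_families

#' Default hyperparameter grids per family
#'
#' The neural grids follow the architecture search ranges of the study
#' design (MLP hidden sizes 300-2500 / 100-500 / 10-75; CNN channels
#' 150-1000, kernel and stride 1-4, fully connected width 50-100; LSTM
#' hidden size 50-300 with dropout 0.7-0.9); the default grid is a small
#' representative subset so that a grid search stays desk-sized. The
#' lasso penalty grid is logarithmic over \code{1e-4 .. 1e1}.
#'
#' @param family Family name.
#' @return Named list of candidate values per hyperparameter.
#' @export
default_grid <- function(family) {
  family <- match.arg(family, classifier_families)
  switch(family,
    lasso_logistic = list(lambda = list(10^seq(-4, 1, length.out = 25L))),
    random_forest = list(num_trees = list(500L)),
    gradient_boosting = list(nrounds = list(500L), max_depth = list(6L)),
    mlp = list(hidden = list(c(300L, 100L, 10L)),
               dropout_input = list(0.7), dropout_hidden = list(0.5),
               bn_momentum = list(0.9)),
    cnn = list(channels = list(c(150L, 150L)), kernel = list(3L),
               stride = list(3L), fc = list(50L), dropout = list(0.2)),
    rnn = list(hidden = list(50L), dropout = list(0.7)),
    rnn_cnn = list(hidden = list(50L), channels = list(c(150L, 150L)),
                   kernel = list(3L), stride = list(3L), fc = list(50L),
                   dropout = list(0.7)))
}

# Architecture search bounds used in strict mode.
grid_bounds <- list(
  mlp = list(hidden1 = c(300, 2500), hidden2 = c(100, 500),
             hidden3 = c(10, 75)),
  cnn = list(channels = c(150, 1000), kernel = c(1, 4), stride = c(1, 4),
             fc = c(50, 100)),
  rnn = list(hidden = c(50, 300), dropout = c(0.7, 0.9)))

check_bounds <- function(family, hp) {
  in_rng <- function(v, r) all(v >= r[1] & v <= r[2])
  msg <- function(what, v, r) {
    stop(sprintf("%s: %s = %s outside the documented grid [%g, %g]",
                 family, what, paste(format(v), collapse = ","),
                 r[1], r[2]), call. = FALSE)
  }
  if (family == "mlp" && !is.null(hp$hidden)) {
    b <- grid_bounds$mlp
    for (i in 1:3) {
      r <- b[[paste0("hidden", i)]]
      if (!in_rng(hp$hidden[i], r)) msg(paste0("hidden layer ", i, " size"),
                                        hp$hidden[i], r)
    }
  }
  if (family == "cnn") {
    b <- grid_bounds$cnn
    if (!is.null(hp$channels) && !in_rng(hp$channels, b$channels))
      msg("channels", hp$channels, b$channels)
    for (nm in c("kernel", "stride", "fc")) {
      if (!is.null(hp[[nm]]) && !in_rng(hp[[nm]], b[[nm]]))
        msg(nm, hp[[nm]], b[[nm]])
    }
  }
  if (family %in% c("rnn", "rnn_cnn")) {
    b <- grid_bounds$rnn
    if (!is.null(hp$hidden) && !in_rng(hp$hidden, b$hidden))
      msg("LSTM hidden size", hp$hidden, b$hidden)
    if (!is.null(hp$dropout) && !in_rng(hp$dropout, b$dropout))
      msg("dropout", hp$dropout, b$dropout)
  }
  invisible(TRUE)
}

#' Specification of one classifier family
#'
#' @param family One of \code{lasso_logistic}, \code{random_forest},
#'   \code{gradient_boosting}, \code{mlp}, \code{cnn}, \code{rnn},
#'   \code{rnn_cnn}.
#' @param grid Hyperparameter grid (named list of candidate-value lists);
#'   default \code{\link{default_grid}}.
#' @param protocol \code{\link{training_protocol}} (ignored by non-neural
#'   families).
#' @param strict Enforce the documented architecture-search bounds
#'   (default \code{TRUE}).
#' @return An object of class \code{"classifier_spec"}.
#' @export
classifier_spec <- function(family, grid = default_grid(family),
                            protocol = training_protocol(), strict = TRUE) {
  family <- match.arg(family, classifier_families)
  if (!length(grid)) stop("hyperparameter grid must be non-empty",
                          call. = FALSE)
  structure(list(family = family, grid = grid, protocol = protocol,
                 strict = strict),
            class = "classifier_spec")
}

#' Build an untrained classifier
#'
#' Instantiates one configuration of a family: linear/tree families carry
#' their backend settings, neural families an initialised layer stack
#' matching the published architectures (MLP: three hidden layers with
#' batch-norm, ReLU and dropout; CNN: two 1-D convolutions and one fully
#' connected hidden layer; RNN: one LSTM plus dropout and a dense output;
#' hybrid: LSTM, two convolutions, one fully connected hidden layer).
#'
#' @param family Family name.
#' @param hyperparameters Named list of one value per hyperparameter.
#' @param n_features Number of one-hot input features (3 x SNPs); needed
#'   to size neural architectures.
#' @param protocol \code{\link{training_protocol}} for neural training.
#' @param strict Enforce grid bounds (default TRUE).
#' @return An object of class \code{c("epibench_classifier", family)}.
#' @export
build_classifier <- function(family, hyperparameters = list(),
                             n_features = NULL,
                             protocol = training_protocol(),
                             strict = TRUE) {
  family <- match.arg(family, classifier_families)
  hp <- hyperparameters
  if (strict) check_bounds(family, hp)
  clf <- list(family = family, hp = hp, protocol = protocol,
              n_features = n_features)
  if (is_neural_family(family)) {
    stopifnot(!is.null(n_features), n_features %% 3L == 0L)
    S <- n_features %/% 3L
    clf$architecture <- switch(family,
      mlp = {
        h <- hp$hidden %||% c(300L, 100L, 10L)
        p1 <- hp$dropout_input %||% 0.7
        p2 <- hp$dropout_hidden %||% 0.5
        mom <- hp$bn_momentum %||% 0.9
        list(nn_dense(n_features, h[1]), nn_batchnorm(h[1], mom), nn_relu(),
             nn_dropout(p1),
             nn_dense(h[1], h[2]), nn_batchnorm(h[2], mom), nn_relu(),
             nn_dropout(p2),
             nn_dense(h[2], h[3]), nn_batchnorm(h[3], mom), nn_relu(),
             nn_dropout(p2),
             nn_dense(h[3], 1L))
      },
      cnn = {
        ch <- hp$channels %||% c(150L, 150L)
        k <- hp$kernel %||% 3L; s <- hp$stride %||% 3L
        fc <- hp$fc %||% 50L; p <- hp$dropout %||% 0.2
        L1 <- (S - k) %/% s + 1L
        L2 <- (L1 - k) %/% s + 1L
        list(nn_to_channels(3L),
             nn_conv1d(3L, ch[1], k, s), nn_relu(),
             nn_conv1d(ch[1], ch[2], k, s), nn_relu(),
             nn_flatten(),
             nn_dense(ch[2] * L2, fc), nn_relu(), nn_dropout(p),
             nn_dense(fc, 1L))
      },
      rnn = {
        h <- hp$hidden %||% 50L; p <- hp$dropout %||% 0.7
        list(nn_to_channels(3L), nn_lstm(3L, h), nn_dropout(p),
             nn_dense(h, 1L))
      },
      rnn_cnn = {
        h <- hp$hidden %||% 50L
        ch <- hp$channels %||% c(150L, 150L)
        k <- hp$kernel %||% 3L; s <- hp$stride %||% 3L
        fc <- hp$fc %||% 50L; p <- hp$dropout %||% 0.7
        L1 <- (S - k) %/% s + 1L
        L2 <- (L1 - k) %/% s + 1L
        list(nn_to_channels(3L), nn_lstm(3L, h, return_sequence = TRUE),
             nn_conv1d(h, ch[1], k, s), nn_relu(),
             nn_conv1d(ch[1], ch[2], k, s), nn_relu(),
             nn_flatten(),
             nn_dense(ch[2] * L2, fc), nn_relu(), nn_dropout(p),
             nn_dense(fc, 1L))
      })
  }
  class(clf) <- c("epibench_classifier", family)
  clf
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit a classifier
#'
#' One uniform contract across families: features are the one-hot matrix,
#' labels 0/1. Neural families additionally require a validation set and
#' are trained with \code{\link{train_neural}}; the lasso penalty is
#' chosen by cross-validation on the training portion over the configured
#' lambda grid unless a single \code{lambda} is supplied.
#'
#' @param clf An object from \code{\link{build_classifier}}.
#' @param X Feature matrix (sparse \code{dgCMatrix} or dense).
#' @param y Labels (0/1).
#' @param X_val,y_val Validation set (neural families only).
#' @param seed Optional integer seed.
#' @return A fitted classifier (class \code{"fitted_classifier"}) with
#'   fields \code{family}, \code{hp}, \code{model}.
#' @export
fit_classifier <- function(clf, X, y, X_val = NULL, y_val = NULL,
                           seed = NULL) {
  stopifnot(inherits(clf, "epibench_classifier"))
  y <- as.integer(y)
  model <- switch(clf$family,
    lasso_logistic = {
      lam <- clf$hp$lambda %||% 10^seq(-4, 1, length.out = 25L)
      lam <- sort(as.numeric(lam), decreasing = TRUE)
      if (length(lam) > 1L) {
        cv <- with_seed(seed, glmnet::cv.glmnet(
          X, y, family = "binomial", lambda = lam, nfolds = 4L,
          type.measure = "auc"))
        list(fit = cv, s = "lambda.min", cv = TRUE)
      } else {
        fit <- glmnet::glmnet(X, y, family = "binomial", lambda = lam)
        list(fit = fit, s = lam, cv = FALSE)
      }
    },
    random_forest = {
      d <- as.data.frame(as.matrix(X))
      d$.y <- factor(y, levels = c(0L, 1L))
      ranger::ranger(
        dependent.variable.name = ".y", data = d, probability = TRUE,
        num.trees = clf$hp$num_trees %||% 500L, num.threads = 1L,
        seed = if (is.null(seed)) NULL else as.integer(seed %% .Machine$integer.max))
    },
    gradient_boosting = {
      params <- list(objective = "binary:logistic",
                     max_depth = clf$hp$max_depth %||% 6L,
                     eta = clf$hp$eta %||% 0.3,
                     nthread = 1L, tree_method = "hist",
                     seed = if (is.null(seed)) 0L
                            else as.integer(seed %% .Machine$integer.max))
      xgboost::xgb.train(params = params,
                         data = xgboost::xgb.DMatrix(X, label = y, nthread = 1L),
                         nrounds = clf$hp$nrounds %||% 500L)
    },
    {
      if (is.null(X_val) || is.null(y_val)) {
        stop(clf$family, " requires a validation set", call. = FALSE)
      }
      layers <- nn_init(clf$architecture,
                        seed = if (is.null(seed)) NULL
                               else derive_seed(seed, "init"))
      train_neural(layers, X, y, X_val, y_val, protocol = clf$protocol,
                   seed = if (is.null(seed)) NULL
                          else derive_seed(seed, "train"))
    })
  structure(list(family = clf$family, hp = clf$hp, model = model,
                 n_features = ncol(X)),
            class = "fitted_classifier")
}

#' Predicted case probabilities
#'
#' @param fitted A \code{fitted_classifier}.
#' @param X Feature matrix.
#' @return Probability vector in \code{[0, 1]}.
#' @export
predict_proba <- function(fitted, X) {
  stopifnot(inherits(fitted, "fitted_classifier"))
  p <- switch(fitted$family,
    lasso_logistic = as.numeric(stats::predict(
      fitted$model$fit, X, s = fitted$model$s, type = "response")),
    random_forest = {
      d <- as.data.frame(as.matrix(X))
      stats::predict(fitted$model, data = d, num.threads = 1L)$predictions[, "1"]
    },
    gradient_boosting = as.numeric(stats::predict(
      fitted$model, xgboost::xgb.DMatrix(X, nthread = 1L))),
    net_predict(fitted$model$layers, X))
  pmin(pmax(as.numeric(p), 0), 1)
}

# Cartesian expansion of a named grid (list of candidate-value lists),
# preserving first-in-grid order.
expand_grid_list <- function(grid) {
  idx <- expand.grid(rev(lapply(grid, seq_along)), KEEP.OUT.ATTRS = FALSE)
  idx <- idx[, rev(seq_along(grid)), drop = FALSE]
  colnames(idx) <- names(grid)
  lapply(seq_len(nrow(idx)), function(r) {
    stats::setNames(lapply(names(grid), function(nm) grid[[nm]][[idx[r, nm]]]),
                    names(grid))
  })
}

#' Exhaustive grid search over a hyperparameter grid
#'
#' Trains one classifier per point of the Cartesian grid and selects the
#' configuration with the highest validation AUC-ROC; ties are broken by
#' first-in-grid order.
#'
#' @param family Classifier family.
#' @param grid Named list of candidate-value lists.
#' @param X,y Training set.
#' @param X_val,y_val Validation set used for selection.
#' @param protocol \code{\link{training_protocol}} for neural families.
#' @param seed Optional integer seed (shared across configurations).
#' @param strict Enforce grid bounds.
#' @return List with \code{best} (fitted classifier),
#'   \code{hyperparameters} (chosen configuration), and \code{log}
#'   (data frame of every configuration and its validation AUC).
#' @export
grid_search <- function(family, grid, X, y, X_val, y_val,
                        protocol = training_protocol(), seed = NULL,
                        strict = TRUE) {
  if (!length(grid)) stop("empty hyperparameter grid", call. = FALSE)
  configs <- expand_grid_list(grid)
  best <- NULL; best_auc <- -Inf; best_hp <- NULL
  log <- NULL
  for (ci in seq_along(configs)) {
    hp <- configs[[ci]]
    clf <- build_classifier(family, hp, n_features = ncol(X),
                            protocol = protocol, strict = strict)
    fitted <- fit_classifier(clf, X, y, X_val, y_val, seed = seed)
    auc <- auc_rank(as.integer(y_val), predict_proba(fitted, X_val))
    log <- rbind(log, data.frame(
      config = ci,
      hyperparameters = paste(names(hp), vapply(hp, function(v)
        paste(format(v), collapse = "x"), character(1)),
        sep = "=", collapse = ", "),
      val_auc = auc))
    if (auc > best_auc) {  # strict >: ties keep the earlier configuration
      best_auc <- auc; best <- fitted; best_hp <- hp
    }
  }
  list(best = best, hyperparameters = best_hp, val_auc = best_auc,
       log = log)
}

#' Read a classifier specification from a configuration file
#'
#' Human-readable YAML with keys \code{family}, optional \code{grid}
#' (named lists of candidate values), optional \code{protocol} (fields of
#' \code{\link{training_protocol}}) and optional \code{strict}.
#'
#' @param path Configuration file path.
#' @return A \code{\link{classifier_spec}}.
#' @export
read_classifier_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$family)) {
    stop("classifier config must name a `family`: ", path, call. = FALSE)
  }
  grid <- if (!is.null(cfg$grid)) {
    lapply(cfg$grid, function(v) if (is.list(v)) v else as.list(v))
  } else default_grid(cfg$family)
  proto <- if (!is.null(cfg$protocol)) {
    do.call(training_protocol, cfg$protocol)
  } else training_protocol()
  classifier_spec(cfg$family, grid = grid, protocol = proto,
                  strict = cfg$strict %||% TRUE)
}

#' Persist / restore a fitted classifier
#'
#' Single-file artifact with the chosen hyperparameters embedded; the
#' neural families store their layer parameters, the backend families
#' their backend model objects (xgboost models are serialised through
#' the backend's raw format so they survive across sessions).
#'
#' @param fitted A \code{fitted_classifier}.
#' @param path Artifact path.
#' @return \code{path} invisibly / the restored \code{fitted_classifier}.
#' @export
save_classifier <- function(fitted, path) {
  stopifnot(inherits(fitted, "fitted_classifier"))
  obj <- fitted
  if (fitted$family == "gradient_boosting") {
    obj$model <- xgboost::xgb.save.raw(fitted$model)
    attr(obj, "xgb_raw") <- TRUE
  }
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  obj <- readRDS(path)
  stopifnot(inherits(obj, "fitted_classifier"))
  if (isTRUE(attr(obj, "xgb_raw"))) {
    obj$model <- xgboost::xgb.load.raw(obj$model)
    attr(obj, "xgb_raw") <- NULL
  }
  obj
}
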