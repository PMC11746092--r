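# Minimal neural-network engine in base R matrix operations.
#
# Supports the four architectures of the model zoo: multilayer perceptron
# (dense + batch-norm + dropout), 1-D CNN over the per-SNP one-hot
# channels, LSTM over the SNP sequence, and the hybrid LSTM + CNN. Trained
# with Adam on binary cross-entropy (computed on logits for stability),
# a cosine-annealed learning rate cycling between two bounds, and early
# stopping on rising validation loss with best-validation-AUC
# checkpointing. Gradients of every layer are validated against finite
# differences in the test suite.

## ---- layer constructors -------------------------------------------------

nn_dense <- function(n_in, n_out) {
  list(type = "dense", n_in = n_in, n_out = n_out,
       params = list(W = matrix(0, n_in, n_out), b = rep(0, n_out)))
}

nn_relu <- function() list(type = "relu", params = list())

nn_dropout <- function(p) {
  stopifnot(p >= 0, p < 1)
  list(type = "dropout", p = p, params = list())
}

nn_batchnorm <- function(n, momentum = 0.9, eps = 1e-5) {
  list(type = "batchnorm", n = n, momentum = momentum, eps = eps,
       params = list(gamma = rep(1, n), beta = rep(0, n)),
       state = list(mean = rep(0, n), var = rep(1, n)))
}

# 1-D convolution over (batch, channels, length) arrays.
nn_conv1d <- function(c_in, c_out, kernel, stride = 1L) {
  list(type = "conv1d", c_in = c_in, c_out = c_out,
       kernel = as.integer(kernel), stride = as.integer(stride),
       params = list(W = array(0, c(kernel * c_in, c_out)), b = rep(0, c_out)))
}

# LSTM over (batch, input, time); returns last hidden state or the full
# hidden sequence as (batch, hidden, time) channels.
nn_lstm <- function(n_in, n_hidden, return_sequence = FALSE) {
  list(type = "lstm", n_in = n_in, n_hidden = n_hidden,
       return_sequence = return_sequence,
       params = list(Wx = matrix(0, n_in, 4L * n_hidden),
                     Wh = matrix(0, n_hidden, 4L * n_hidden),
                     b = rep(0, 4L * n_hidden)))
}

# Reshape a one-hot (batch, 3*S) matrix to channel layout (batch, 3, S).
nn_to_channels <- function(n_channels = 3L) {
  list(type = "to_channels", n_channels = as.integer(n_channels),
       params = list())
}

nn_flatten <- function() list(type = "flatten", params = list())

## ---- initialisation -----------------------------------------------------

nn_init <- function(layers, seed = NULL) {
  with_seed(seed, {
    for (i in seq_along(layers)) {
      ly <- layers[[i]]
      if (ly$type == "dense") {
        ly$params$W[] <- stats::rnorm(length(ly$params$W)) *
          sqrt(2 / ly$n_in)
      } else if (ly$type == "conv1d") {
        ly$params$W[] <- stats::rnorm(length(ly$params$W)) *
          sqrt(2 / (ly$kernel * ly$c_in))
      } else if (ly$type == "lstm") {
        sc <- 1 / sqrt(ly$n_hidden)
        ly$params$Wx[] <- stats::runif(length(ly$params$Wx), -sc, sc)
        ly$params$Wh[] <- stats::runif(length(ly$params$Wh), -sc, sc)
        # forget-gate bias starts at 1 (standard recipe)
        ly$params$b[ly$n_hidden + seq_len(ly$n_hidden)] <- 1
      }
      layers[[i]] <- ly
    }
    layers
  })
}

## ---- forward / backward -------------------------------------------------

sigmoid <- function(z) stats::plogis(z)

# conv helper: column indices of the receptive field for each output pos
conv_field <- function(L, kernel, stride) {
  L_out <- (L - kernel) %/% stride + 1L
  if (L_out < 1L) stop("conv1d: kernel longer than input", call. = FALSE)
  pos <- outer(seq_len(kernel), (seq_len(L_out) - 1L) * stride, `+`) # K x L_out
  list(L_out = L_out, pos = pos)
}

layer_forward <- function(ly, x, training = FALSE) {
  cache <- NULL
  out <- switch(ly$type,
    dense = {
      cache <- list(x = x)
      sweep(x %*% ly$params$W, 2L, ly$params$b, `+`)
    },
    relu = {
      m <- x > 0
      cache <- list(mask = m)
      x * m
    },
    dropout = {
      if (training && ly$p > 0) {
        mask <- (array(stats::runif(length(x)), dim = dim2(x)) >= ly$p) /
          (1 - ly$p)
        cache <- list(mask = mask)
        x * mask
      } else {
        cache <- list(mask = NULL)
        x
      }
    },
    batchnorm = {
      if (training) {
        mu <- colMeans(x)
        v <- colMeans(sweep(x, 2L, mu)^2)
        ly$state$mean <- ly$momentum * ly$state$mean + (1 - ly$momentum) * mu
        ly$state$var <- ly$momentum * ly$state$var + (1 - ly$momentum) * v
      } else {
        mu <- ly$state$mean
        v <- ly$state$var
      }
      xh <- sweep(sweep(x, 2L, mu), 2L, sqrt(v + ly$eps), `/`)
      cache <- list(xh = xh, v = v, training = training)
      sweep(sweep(xh, 2L, ly$params$gamma, `*`), 2L, ly$params$beta, `+`)
    },
    to_channels = {
      B <- nrow(x); C <- ly$n_channels
      stopifnot(ncol(x) %% C == 0L)
      cache <- list(dims = dim(x))
      array(as.numeric(x), c(B, C, ncol(x) %/% C))
    },
    flatten = {
      cache <- list(dims = dim(x))
      d <- dim(x)
      dim(x) <- c(d[1L], prod(d[-1L]))
      x
    },
    conv1d = {
      d <- dim(x)  # B, C_in, L
      fld <- conv_field(d[3L], ly$kernel, ly$stride)
      # X columns: (B*L_out) x (K*C_in), receptive fields as rows
      xp <- x[, , as.vector(fld$pos), drop = FALSE]      # B, C_in, K*L_out
      dim(xp) <- c(d[1L], d[2L], ly$kernel, fld$L_out)
      xp <- aperm(xp, c(1L, 4L, 3L, 2L))                 # B, L_out, K, C_in
      dim(xp) <- c(d[1L] * fld$L_out, ly$kernel * d[2L])
      z <- sweep(xp %*% ly$params$W, 2L, ly$params$b, `+`)  # (B*L_out) x C_out
      cache <- list(xcol = xp, in_dim = d, fld = fld)
      dim(z) <- c(d[1L], fld$L_out, ly$c_out)
      aperm(z, c(1L, 3L, 2L))                            # B, C_out, L_out
    },
    lstm = {
      d <- dim(x)  # B, D, T
      B <- d[1L]; Tt <- d[3L]; H <- ly$n_hidden
      h <- matrix(0, B, H); cc <- matrix(0, B, H)
      gates <- vector("list", Tt); cs <- vector("list", Tt)
      hs <- vector("list", Tt)
      seq_out <- if (ly$return_sequence) array(0, c(B, H, Tt)) else NULL
      for (t in seq_len(Tt)) {
        xt <- matrix(x[, , t], B)
        z <- xt %*% ly$params$Wx + h %*% ly$params$Wh +
          matrix(ly$params$b, B, 4L * H, byrow = TRUE)
        i <- sigmoid(z[, seq_len(H), drop = FALSE])
        f <- sigmoid(z[, H + seq_len(H), drop = FALSE])
        g <- tanh(z[, 2L * H + seq_len(H), drop = FALSE])
        o <- sigmoid(z[, 3L * H + seq_len(H), drop = FALSE])
        cc_new <- f * cc + i * g
        h_new <- o * tanh(cc_new)
        gates[[t]] <- list(i = i, f = f, g = g, o = o, c_prev = cc,
                           h_prev = h, xt = xt)
        cs[[t]] <- cc_new
        hs[[t]] <- h_new
        h <- h_new; cc <- cc_new
        if (ly$return_sequence) seq_out[, , t] <- h_new
      }
      cache <- list(gates = gates, cs = cs, in_dim = d)
      if (ly$return_sequence) seq_out else h
    },
    stop("unknown layer type: ", ly$type))
  list(out = out, cache = cache, layer = ly)
}

dim2 <- function(x) if (is.null(dim(x))) length(x) else dim(x)

layer_backward <- function(ly, cache, dout) {
  switch(ly$type,
    dense = list(dx = dout %*% t(ly$params$W),
                 grads = list(W = crossprod(cache$x, dout),
                              b = colSums(dout))),
    relu = list(dx = dout * cache$mask, grads = list()),
    dropout = list(dx = if (is.null(cache$mask)) dout else dout * cache$mask,
                   grads = list()),
    batchnorm = {
      B <- nrow(cache$xh)
      dgamma <- colSums(dout * cache$xh)
      dbeta <- colSums(dout)
      dxh <- sweep(dout, 2L, ly$params$gamma, `*`)
      inv_sd <- 1 / sqrt(cache$v + ly$eps)
      if (cache$training) {
        dx <- sweep(
          dxh - matrix(colMeans(dxh), B, ncol(dxh), byrow = TRUE) -
            sweep(cache$xh, 2L, colMeans(dxh * cache$xh), `*`),
          2L, inv_sd, `*`)
      } else {
        dx <- sweep(dxh, 2L, inv_sd, `*`)
      }
      list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
    },
    to_channels = {
      dim(dout) <- cache$dims
      list(dx = dout, grads = list())
    },
    flatten = {
      dim(dout) <- cache$dims
      list(dx = dout, grads = list())
    },
    conv1d = {
      d <- cache$in_dim; fld <- cache$fld
      dz <- aperm(dout, c(1L, 3L, 2L))                 # B, L_out, C_out
      dim(dz) <- c(d[1L] * fld$L_out, ly$c_out)
      gW <- crossprod(cache$xcol, dz)
      gb <- colSums(dz)
      dxcol <- dz %*% t(ly$params$W)                   # (B*L_out) x (K*C_in)
      dim(dxcol) <- c(d[1L], fld$L_out, ly$kernel, d[2L])
      dxcol <- aperm(dxcol, c(1L, 4L, 3L, 2L))         # B, C_in, K, L_out
      dx <- array(0, d)
      for (k in seq_len(ly$kernel)) {
        idx <- fld$pos[k, ]
        slice <- dxcol[, , k, , drop = FALSE]
        dim(slice) <- dim(slice)[c(1L, 2L, 4L)]
        dx[, , idx] <- dx[, , idx, drop = FALSE] + slice
      }
      list(dx = dx, grads = list(W = gW, b = gb))
    },
    lstm = {
      d <- cache$in_dim
      B <- d[1L]; Tt <- d[3L]; H <- ly$n_hidden
      seq_grad <- ly$return_sequence
      dh_next <- if (seq_grad) matrix(0, B, H) else dout
      dc_next <- matrix(0, B, H)
      gWx <- 0 * ly$params$Wx; gWh <- 0 * ly$params$Wh
      gb <- 0 * ly$params$b
      dx <- array(0, d)
      for (t in rev(seq_len(Tt))) {
        gt <- cache$gates[[t]]
        ct <- cache$cs[[t]]
        dh <- dh_next + if (seq_grad) matrix(dout[, , t], B) else 0
        tc <- tanh(ct)
        do_ <- dh * tc
        dc <- dh * gt$o * (1 - tc^2) + dc_next
        di <- dc * gt$g
        df <- dc * gt$c_prev
        dg <- dc * gt$i
        dzi <- di * gt$i * (1 - gt$i)
        dzf <- df * gt$f * (1 - gt$f)
        dzg <- dg * (1 - gt$g^2)
        dzo <- do_ * gt$o * (1 - gt$o)
        dz <- cbind(dzi, dzf, dzg, dzo)
        gWx <- gWx + crossprod(gt$xt, dz)
        gWh <- gWh + crossprod(gt$h_prev, dz)
        gb <- gb + colSums(dz)
        dx[, , t] <- dz %*% t(ly$params$Wx)
        dh_next <- dz %*% t(ly$params$Wh)
        dc_next <- dc * gt$f
      }
      list(dx = dx, grads = list(Wx = gWx, Wh = gWh, b = gb))
    },
    stop("unknown layer type: ", ly$type))
}

net_forward <- function(layers, x, training = FALSE) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    r <- layer_forward(layers[[i]], x, training)
    x <- r$out
    caches[[i]] <- r$cache
    layers[[i]] <- r$layer
  }
  list(out = x, caches = caches, layers = layers)
}

net_backward <- function(layers, caches, dout) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    r <- layer_backward(layers[[i]], caches[[i]], dout)
    dout <- r$dx
    grads[[i]] <- r$grads
  }
  grads
}

# Forward pass producing probabilities, batched to bound memory.
net_predict <- function(layers, X, batch_size = 2048L) {
  n <- nrow(X)
  out <- numeric(n)
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    xb <- as.matrix(X[idx, , drop = FALSE])
    out[idx] <- sigmoid(drop(net_forward(layers, xb, training = FALSE)$out))
  }
  out
}

## ---- optimiser and schedule ---------------------------------------------

adam_init <- function(layers) {
  lapply(layers, function(ly)
    lapply(ly$params, function(p) list(m = 0 * p, v = 0 * p)))
}

adam_step <- function(layers, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (i in seq_along(layers)) {
    for (nm in names(grads[[i]])) {
      g <- grads[[i]][[nm]]
      st <- state[[i]][[nm]]
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g^2
      mhat <- st$m / (1 - beta1^t)
      vhat <- st$v / (1 - beta2^t)
      layers[[i]]$params[[nm]] <- layers[[i]]$params[[nm]] -
        lr * mhat / (sqrt(vhat) + eps)
      state[[i]][[nm]] <- st
    }
  }
  list(layers = layers, state = state)
}

#' Cosine-annealed cyclic learning rate
#'
#' The learning rate starts each cycle at \code{lr_max} and follows a
#' cosine decay to \code{lr_min} over \code{period} epochs, restarting
#' every \code{period} epochs.
#'
#' @param epoch Epoch number (1-based).
#' @param lr_max,lr_min Cycle bounds (defaults \code{1e-3}, \code{1e-4}).
#' @param period Cycle length in epochs (default 10).
#' @return Learning rate for that epoch.
#' @export
cosine_lr <- function(epoch, lr_max = 1e-3, lr_min = 1e-4, period = 10L) {
  phase <- ((epoch - 1) %% period) / period
  lr_min + (lr_max - lr_min) * (1 + cos(pi * phase)) / 2
}

bce_with_logits <- function(logits, y) {
  # mean softplus(z) - y z, computed stably
  mean(pmax(logits, 0) - logits * y + log1p(exp(-abs(logits))))
}

#' Training protocol for the neural families
#'
#' @param epochs Epoch budget (default 30).
#' @param batch_size Minibatch size (default 256).
#' @param lr_max,lr_min,lr_period Cosine learning-rate cycle (defaults
#'   \code{1e-3} to \code{1e-4} over 10 epochs).
#' @param patience Early stopping: training halts after more than
#'   \code{patience} consecutive epochs of rising validation loss
#'   (default 5).
#' @return A list of class \code{"training_protocol"}.
#' @export
training_protocol <- function(epochs = 30L, batch_size = 256L,
                              lr_max = 1e-3, lr_min = 1e-4,
                              lr_period = 10L, patience = 5L) {
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 lr_max = lr_max, lr_min = lr_min,
                 lr_period = as.integer(lr_period),
                 patience = as.integer(patience)),
            class = "training_protocol")
}

#' Train a neural classifier with Adam, cosine LR and early stopping
#'
#' Minimises binary cross-entropy with the Adam optimizer; the learning
#' rate follows \code{\link{cosine_lr}}. Validation loss and AUC-ROC are
#' recorded every epoch; training stops early once validation loss has
#' risen for more than \code{protocol$patience} consecutive epochs, and
#' the parameters from the epoch with the best validation AUC-ROC are
#' restored.
#'
#' @param layers An initialised layer list (see \code{\link{build_classifier}}).
#' @param X,y Training features (dense or \code{Matrix} sparse) and 0/1
#'   labels.
#' @param X_val,y_val Validation set (disjoint from training).
#' @param protocol A \code{\link{training_protocol}}.
#' @param seed Optional integer seed controlling shuffling, dropout and
#'   initial state.
#' @return List with \code{layers} (best checkpoint), \code{history}
#'   (per-epoch data frame: epoch, lr, train_loss, val_loss, val_auc),
#'   \code{best_epoch}, \code{stopped_early}.
#' @export
train_neural <- function(layers, X, y, X_val, y_val,
                         protocol = training_protocol(), seed = NULL) {
  if (nrow(X) == 0L || length(y) == 0L) stop("empty training set", call. = FALSE)
  if (nrow(X_val) == 0L) stop("empty validation set", call. = FALSE)
  y <- as.numeric(y)
  n <- nrow(X)
  state <- adam_init(layers)
  history <- NULL
  best <- list(auc = -Inf, layers = layers, epoch = 0L)
  prev_val_loss <- Inf
  rising <- 0L
  stopped <- FALSE
  step <- 0L
  with_seed(seed, {
    for (epoch in seq_len(protocol$epochs)) {
      lr <- cosine_lr(epoch, protocol$lr_max, protocol$lr_min,
                      protocol$lr_period)
      ord <- sample.int(n)
      tl <- 0; nb <- 0L
      for (start in seq(1L, n, by = protocol$batch_size)) {
        idx <- ord[start:min(start + protocol$batch_size - 1L, n)]
        if (length(idx) < 2L) next  # batch-norm needs > 1 sample
        xb <- as.matrix(X[idx, , drop = FALSE])
        fwd <- net_forward(layers, xb, training = TRUE)
        layers <- fwd$layers
        z <- drop(fwd$out)
        if (any(!is.finite(z))) stop("training diverged: non-finite logits",
                                     call. = FALSE)
        tl <- tl + bce_with_logits(z, y[idx]); nb <- nb + 1L
        dz <- matrix((sigmoid(z) - y[idx]) / length(idx), ncol = 1L)
        grads <- net_backward(layers, fwd$caches, dz)
        step <- step + 1L
        upd <- adam_step(layers, grads, state, lr, step)
        layers <- upd$layers
        state <- upd$state
      }
      pv <- net_predict(layers, X_val)
      val_loss <- bce_with_logits(stats::qlogis(pmin(pmax(pv, 1e-12), 1 - 1e-12)),
                                  as.numeric(y_val))
      val_auc <- auc_rank(as.integer(y_val), pv)
      history <- rbind(history, data.frame(
        epoch = epoch, lr = lr, train_loss = tl / max(nb, 1L),
        val_loss = val_loss, val_auc = val_auc))
      if (val_auc > best$auc) {
        best <- list(auc = val_auc, layers = layers, epoch = epoch)
      }
      rising <- if (val_loss > prev_val_loss) rising + 1L else 0L
      prev_val_loss <- val_loss
      if (rising > protocol$patience) {
        stopped <- TRUE
        break
      }
    }
  })
  list(layers = best$layers, history = history, best_epoch = best$epoch,
       stopped_early = stopped)
}
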