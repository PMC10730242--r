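# Supervised encoder MLP. A small feed-forward regression network
# (input -> 32 -> 16 -> bottleneck -> 1) trained on standardized
# c-IMT_mean-max by minibatch Adam with early stopping on a held-out
# validation split. Hidden layers are leaky rectifiers; the bottleneck is a
# saturating tanh code whose activations are the atherosclerosis-guided
# embedding handed to the clustering stage. Saturation quantizes the
# outcome-related manifold into discrete activation patterns, which is what
# lets hierarchical clustering see discrete endotypes; variation unrelated
# to the outcome is filtered out because it does not help the regression
# head. Gaussian input-noise augmentation is the main regularizer: with a
# weak, low signal-to-noise supervision target the un-regularized network
# memorizes the training fold within a few epochs.

#' Encoder MLP hyperparameters
#'
#' @param hidden Widths of the two leaky-rectified hidden layers.
#' @param bottleneck Embedding dimension (tanh layer).
#' @param lr Adam learning rate.
#' @param weight_decay Decoupled L2 weight decay on the weight matrices.
#' @param batch_size Minibatch size.
#' @param max_epochs Epoch cap.
#' @param patience Early-stopping patience (epochs without validation
#'   improvement).
#' @param val_frac Fraction of rows held out for validation.
#' @param input_noise SD of Gaussian noise added to (standardized) inputs of
#'   every minibatch during training; the default is deliberately strong,
#'   matched to the weak supervision signal of the endotyping task. Set
#'   lower for high signal-to-noise regressions.
#' @param code_pressure Weight of the code-decisiveness penalty
#'   `mean(1 - B^2)` on the bottleneck activations `B`, which pulls codes
#'   toward saturation at +-1 so the outcome-related manifold quantizes
#'   into discrete activation patterns. Set 0 to disable.
#' @param min_signal Minimum relative validation-MSE improvement over the
#'   untrained network required to keep the trained weights. When training
#'   never beats the untrained model by this margin (as with an
#'   uninformative outcome), the untrained weights are returned and the
#'   model is flagged `reverted` - saturation and any structure it creates
#'   must be earned by the supervision signal.
#' @return A list of hyperparameters.
#' @export
encoder_hparams <- function(hidden = c(32, 16), bottleneck = 8, lr = 3e-3,
                            weight_decay = 1e-3, batch_size = 256,
                            max_epochs = 600, patience = 100, val_frac = 0.2,
                            input_noise = 1.5, code_pressure = 0.03,
                            min_signal = 0.05) {
  stopifnot(length(hidden) >= 1, bottleneck >= 1, lr > 0, batch_size >= 1,
            max_epochs >= 1, patience >= 1, val_frac > 0, val_frac < 1,
            input_noise >= 0, code_pressure >= 0,
            min_signal >= 0, min_signal < 1)
  list(hidden = as.integer(hidden), bottleneck = as.integer(bottleneck),
       lr = lr, weight_decay = weight_decay,
       batch_size = as.integer(batch_size),
       max_epochs = as.integer(max_epochs), patience = as.integer(patience),
       val_frac = val_frac, input_noise = input_noise,
       code_pressure = code_pressure, min_signal = min_signal)
}

# Semi-orthogonal random matrix (columns or rows orthonormal) scaled by
# `gain`. Orthogonal initialization keeps the untrained network an isotropic
# projection: the composed layers do not concentrate their spectrum, so the
# untrained embedding of an unstructured cloud stays an unstructured cloud.
orthogonal_init <- function(fan_in, fan_out, gain) {
  if (fan_in >= fan_out) {
    Q <- qr.Q(qr(matrix(stats::rnorm(fan_in * fan_out), fan_in)))
  } else {
    Q <- t(qr.Q(qr(matrix(stats::rnorm(fan_out * fan_in), fan_out))))
  }
  gain * Q
}

encoder_init <- function(p, hp, ...) {
  dims <- c(p, hp$hidden, hp$bottleneck, 1L)
  L <- length(dims) - 1L
  W <- list(); b <- list()
  for (l in seq_len(L)) {
    # The tanh bottleneck and the head start small (gain 0.1), in the linear
    # regime: saturation - and any discrete structure it creates in the
    # embedding - must be earned by the supervision signal, never injected
    # by the initialization.
    gain <- if (l >= L - 1L) 0.1 else 1.0
    W[[l]] <- orthogonal_init(dims[l], dims[l + 1L], gain)
    b[[l]] <- rep(0, dims[l + 1L])
  }
  list(W = W, b = b, dims = dims)
}

leaky_slope <- 0.3
lrelu <- function(x) ifelse(x > 0, x, leaky_slope * x)
dlrelu_post <- function(a_post) ifelse(a_post > 0, 1, leaky_slope)

# Forward pass; returns activations per layer. Hidden layers are leaky
# rectifiers, the bottleneck (layer L-1) is tanh, the head is linear.
encoder_forward <- function(par, X) {
  L <- length(par$W)
  A <- vector("list", L + 1L)
  A[[1L]] <- X
  for (l in seq_len(L)) {
    Zl <- sweep(A[[l]] %*% par$W[[l]], 2, par$b[[l]], "+")
    A[[l + 1L]] <- if (l == L) Zl else if (l == L - 1L) tanh(Zl) else lrelu(Zl)
  }
  A
}

encoder_backward <- function(par, A, y, code_pressure = 0) {
  L <- length(par$W)
  m <- nrow(A[[1L]])
  gW <- vector("list", L); gb <- vector("list", L)
  delta <- (A[[L + 1L]] - y) * (2 / m)   # d mean((yhat-y)^2) / d yhat
  for (l in rev(seq_len(L))) {
    gW[[l]] <- crossprod(A[[l]], delta)
    gb[[l]] <- colSums(delta)
    if (l > 1L) {
      delta <- delta %*% t(par$W[[l]])
      if (l == L) {
        B <- A[[l]]
        # Decisiveness pressure: gradient of
        # code_pressure * sum_j r_j (1 - B_j^2), pulling bottleneck codes
        # toward saturation at +-1. Each unit's pressure is weighted by the
        # relevance r_j = |head weight_j| / sum |head weights|: units the
        # regression head relies on are driven to decisive (quantized)
        # states, while unused units feel no pressure and simply decay.
        if (code_pressure > 0) {
          w_head <- abs(par$W[[L]][, 1L])
          r <- w_head / (sum(w_head) + 1e-12)
          delta <- delta - code_pressure * 2 *
            sweep(B, 2L, r, "*") / m
        }
        delta <- delta * (1 - B^2)
      } else {
        delta <- delta * dlrelu_post(A[[l]])
      }
    }
  }
  list(W = gW, b = gb)
}

#' Train the supervised encoder MLP
#'
#' Minimizes mean squared error of the regression head on the supplied
#' outcome, with minibatch Adam, decoupled weight decay and early stopping on
#' a seeded validation split. The run is fully reproducible for a fixed seed.
#'
#' @param table Numeric data frame or matrix of (standardized) features; no
#'   missing values.
#' @param outcome Numeric outcome aligned to the rows (standardized
#'   c-IMT_mean-max in the endotyping pipeline).
#' @param hparams See [encoder_hparams()].
#' @param seed Integer seed controlling initialization, the validation split
#'   and minibatch shuffling.
#' @return An `encoder_mlp` object with the best-epoch weights, the feature
#'   schema, the epoch-by-epoch training log and validation indices.
#' @export
train_encoder <- function(table, outcome, hparams = encoder_hparams(), seed = 1) {
  X <- as.matrix(table)
  storage.mode(X) <- "double"
  y <- as.numeric(outcome)
  if (nrow(X) != length(y)) abort_endo("`outcome` must align with the rows of `table`.")
  if (!all(is.finite(X)) || !all(is.finite(y))) {
    abort_endo("Features and outcome must be finite (no missing values).")
  }
  if (nrow(X) <= hparams$bottleneck) {
    abort_endo("Fewer subjects than the bottleneck dimension.")
  }
  p <- ncol(X)

  with_seed(sub_seed(seed, "encoder"), {
    n <- nrow(X)
    n_val <- max(1L, floor(hparams$val_frac * n))
    val_idx <- sample.int(n, n_val)
    tr_idx <- setdiff(seq_len(n), val_idx)
    Xtr <- X[tr_idx, , drop = FALSE]; ytr <- y[tr_idx]
    Xval <- X[val_idx, , drop = FALSE]; yval <- y[val_idx]

    par <- encoder_init(p, hparams)
    init_par <- par
    L <- length(par$W)
    mW <- lapply(par$W, function(w) w * 0); vW <- mW
    mb <- lapply(par$b, function(b) b * 0); vb <- mb
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; t_step <- 0
    lr <- hparams$lr; wd <- hparams$weight_decay

    val_loss_of <- function(par) {
      pred <- encoder_forward(par, Xval)[[L + 1L]]
      mean((pred - yval)^2)
    }
    val_init <- val_loss_of(par)
    best <- list(par = par, val = val_init, epoch = 0L)
    log_epoch <- integer(0); log_train <- numeric(0); log_val <- numeric(0)
    stale <- 0L
    ntr <- nrow(Xtr)

    for (epoch in seq_len(hparams$max_epochs)) {
      ord <- sample.int(ntr)
      tr_loss_sum <- 0; tr_n <- 0
      for (start in seq(1L, ntr, by = hparams$batch_size)) {
        idx <- ord[start:min(start + hparams$batch_size - 1L, ntr)]
        Xb <- Xtr[idx, , drop = FALSE]; yb <- ytr[idx]
        if (hparams$input_noise > 0) {
          Xb <- Xb + matrix(stats::rnorm(length(Xb), 0, hparams$input_noise),
                            nrow = nrow(Xb))
        }
        A <- encoder_forward(par, Xb)
        pred <- A[[L + 1L]]
        tr_loss_sum <- tr_loss_sum + sum((pred - yb)^2)
        tr_n <- tr_n + length(idx)
        g <- encoder_backward(par, A, yb, hparams$code_pressure)
        t_step <- t_step + 1
        corr1 <- 1 - b1^t_step; corr2 <- 1 - b2^t_step
        for (l in seq_len(L)) {
          mW[[l]] <- b1 * mW[[l]] + (1 - b1) * g$W[[l]]
          vW[[l]] <- b2 * vW[[l]] + (1 - b2) * g$W[[l]]^2
          par$W[[l]] <- par$W[[l]] -
            lr * ((mW[[l]] / corr1) / (sqrt(vW[[l]] / corr2) + eps) +
                    wd * par$W[[l]])
          mb[[l]] <- b1 * mb[[l]] + (1 - b1) * g$b[[l]]
          vb[[l]] <- b2 * vb[[l]] + (1 - b2) * g$b[[l]]^2
          par$b[[l]] <- par$b[[l]] -
            lr * (mb[[l]] / corr1) / (sqrt(vb[[l]] / corr2) + eps)
        }
      }
      vl <- val_loss_of(par)
      log_epoch <- c(log_epoch, epoch)
      log_train <- c(log_train, tr_loss_sum / tr_n)
      log_val <- c(log_val, vl)
      if (vl < best$val - 1e-9) {
        best <- list(par = par, val = vl, epoch = epoch)
        stale <- 0L
      } else {
        stale <- stale + 1L
        if (stale >= hparams$patience) break
      }
    }

    # Keep the trained weights only if validation improved meaningfully over
    # the untrained network; otherwise the outcome carried no learnable
    # signal and the honest representation is the untrained one.
    reverted <- best$val > (1 - hparams$min_signal) * val_init
    if (reverted) best <- list(par = init_par, val = val_init, epoch = 0L)

    structure(list(
      par = best$par,
      dims = best$par$dims,
      features = colnames(X),
      bottleneck = hparams$bottleneck,
      log = tibble::tibble(epoch = log_epoch, train_loss = log_train,
                           val_loss = log_val),
      best_epoch = best$epoch,
      val_loss = best$val,
      val_idx = val_idx,
      val_r2 = 1 - best$val / max(stats::var(yval), 1e-12),
      reverted = reverted,
      hparams = hparams,
      seed = as.integer(seed)
    ), class = "encoder_mlp")
  })
}

#' @export
print.encoder_mlp <- function(x, ...) {
  cat(sprintf("<encoder_mlp> %s, best epoch %d, val MSE %.4f (R^2 %.3f)\n",
              paste(x$dims, collapse = " -> "), x$best_epoch, x$val_loss,
              x$val_r2))
  invisible(x)
}

#' Training log of an encoder MLP
#' @param x An `encoder_mlp`.
#' @param ... Unused.
#' @return Tibble with `epoch`, `train_loss`, `val_loss`.
#' @method tidy encoder_mlp
#' @export
tidy.encoder_mlp <- function(x, ...) x$log

#' One-row model summary of an encoder MLP
#' @param x An `encoder_mlp`.
#' @param ... Unused.
#' @return Tibble with best epoch, validation MSE and validation R-squared.
#' @method glance encoder_mlp
#' @export
glance.encoder_mlp <- function(x, ...) {
  tibble::tibble(best_epoch = x$best_epoch, val_mse = x$val_loss,
                 val_r2 = x$val_r2, n_epochs_run = nrow(x$log))
}

check_schema <- function(model, X) {
  if (!is.null(model$features) && !is.null(colnames(X))) {
    if (!identical(colnames(X), model$features)) {
      if (all(model$features %in% colnames(X))) {
        return(X[, model$features, drop = FALSE])
      }
      abort_endo("Feature schema does not match the training schema.")
    }
  } else if (ncol(X) != model$dims[1L]) {
    abort_endo("Feature schema does not match the training schema.")
  }
  X
}

#' Predict the regression head of an encoder MLP
#' @param object An `encoder_mlp`.
#' @param newdata Numeric data frame / matrix matching the training schema.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.encoder_mlp <- function(object, newdata, ...) {
  X <- as.matrix(newdata); storage.mode(X) <- "double"
  X <- check_schema(object, X)
  if (!all(is.finite(X))) abort_endo("`newdata` must be finite.")
  A <- encoder_forward(object$par, X)
  as.numeric(A[[length(object$par$W) + 1L]])
}

#' Bottleneck embedding of an encoder MLP
#'
#' Deterministic forward pass to the bottleneck layer.
#'
#' @param model An `encoder_mlp`.
#' @param table Numeric data frame / matrix matching the training schema.
#' @return Tibble with columns `dim_1` .. `dim_d` (one row per input row).
#' @export
embed <- function(model, table) {
  stopifnot(inherits(model, "encoder_mlp"))
  X <- as.matrix(table); storage.mode(X) <- "double"
  X <- check_schema(model, X)
  if (!all(is.finite(X))) abort_endo("`table` must be finite.")
  A <- encoder_forward(model$par, X)
  B <- A[[length(model$par$W)]]   # layer before the regression head
  colnames(B) <- paste0("dim_", seq_len(ncol(B)))
  tibble::as_tibble(B)
}

#' Random-outcome null control
#'
#' Re-runs the representation-learning and clustering stages with a
#' Uniform(0, 1) outcome in place of c-IMT_mean-max. With no learnable
#' signal the embedding should show no cluster structure: the report carries
#' the silhouette profile over k = 2..kmax and a verdict (`structure` is
#' `TRUE` only when the maximum mean silhouette reaches `threshold`).
#'
#' @param table Numeric feature table (standardized), no missing values.
#' @param seed Integer seed for the null outcome and the encoder.
#' @param hparams Encoder hyperparameters.
#' @param kmin,kmax Cluster-number grid.
#' @param threshold Silhouette level below which the verdict is
#'   "no defined cluster".
#' @return List with `max_silhouette`, `k_best`, `structure`, `verdict` and
#'   the full `profile` tibble.
#' @export
null_control <- function(table, seed = 1, hparams = encoder_hparams(),
                         kmin = 2, kmax = 8, threshold = 0.15) {
  X <- as.matrix(table)
  y0 <- generate_null_outcome(nrow(X), seed)
  y <- if (stats::sd(y0) > 0) (y0 - mean(y0)) / stats::sd(y0) else y0 * 0
  model <- train_encoder(X, y, hparams = hparams, seed = seed)
  emb <- embed(model, X)
  prof <- select_k(emb, kmin = kmin, kmax = kmax, threshold = threshold)
  list(max_silhouette = prof$max_silhouette,
       k_best = prof$k,
       structure = !prof$no_structure,
       verdict = if (prof$no_structure) "no defined cluster" else "structure",
       profile = prof$profile)
}
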