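# Minimal feed-forward network machinery: He-uniform initialization,
# forward pass, mini-batch Adam training with MSE loss, early stopping.
# Each neuron computes y_j = F(sum_i w_ij x_i + b_j) with F either the
# rectifier or the identity; this is all the architecture the pipeline
# needs (no convolution, dropout or regularization).

#' Training configuration for mini-batch MSE training
#'
#' @param learning_rate Adam step size (default 1e-3).
#' @param beta1,beta2,adam_eps Adam moment decay rates and ridge
#'   (defaults 0.9 / 0.999 / 1e-8).
#' @param batch_size mini-batch size (default 64).
#' @param max_epochs maximum number of epochs.
#' @param patience early-stopping patience: training halts once the
#'   validation loss has failed to improve (strictly) for this many
#'   consecutive epochs. `NULL` disables early stopping.
#' @param restore_best if `TRUE`, return the parameters from the epoch with
#'   the best validation loss instead of the parameters at the stop.
#' @param seed integer seed controlling initial shuffling; runs are
#'   bit-reproducible given (seed, batch_size).
#' @return a list of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-3, beta1 = 0.9, beta2 = 0.999,
                         adam_eps = 1e-8, batch_size = 64, max_epochs = 100,
                         patience = NULL, restore_best = FALSE, seed = 1L) {
  if (batch_size < 1) stop_validation("batch_size must be >= 1")
  if (!is.null(patience) && patience < 1) stop_validation("patience must be >= 1")
  structure(list(learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
                 adam_eps = adam_eps, batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs), patience = patience,
                 restore_best = isTRUE(restore_best), seed = as.integer(seed)),
            class = "train_config")
}

#' He-uniform initialization of a layer chain
#'
#' Weights of each layer are drawn uniformly from \[-L, L\] with
#' L = sqrt(6 / fan_in), the initialization recommended for rectifier
#' networks; biases start at zero. Deterministic given `seed`.
#'
#' @param layer_dims integer vector of layer widths, input first
#'   (e.g., `c(300, 64, 16)` for a 300-input, 16-output network).
#' @param activations activation tag per weight layer (`length(layer_dims) - 1`
#'   entries of `"relu"` or `"linear"`); defaults to relu on hidden layers
#'   and linear on the output layer.
#' @param seed integer seed.
#' @return an object of class `mlp_params`: a list of layers, each holding
#'   a `fan_out x fan_in` weight matrix `W`, a bias vector `b` and an
#'   `activation` tag.
#' @export
he_uniform_init <- function(layer_dims, activations = NULL, seed = 1L) {
  n_layers <- length(layer_dims) - 1L
  if (n_layers < 1) stop_validation("need at least an input and an output layer")
  if (any(layer_dims < 1)) stop_validation("all layer widths must be >= 1")
  if (is.null(activations))
    activations <- c(rep("relu", max(0L, n_layers - 1L)), "linear")
  if (length(activations) != n_layers)
    stop_validation("need one activation per weight layer")
  if (!all(activations %in% c("relu", "linear")))
    stop_validation("activations must be 'relu' or 'linear'")
  set.seed(as.integer(seed))
  layers <- vector("list", n_layers)
  for (l in seq_len(n_layers)) {
    fan_in <- layer_dims[l]; fan_out <- layer_dims[l + 1L]
    L <- sqrt(6 / fan_in)
    layers[[l]] <- list(
      W = matrix(stats::runif(fan_out * fan_in, -L, L), fan_out, fan_in),
      b = numeric(fan_out),
      activation = activations[l]
    )
  }
  structure(layers, class = "mlp_params")
}

#' Layer widths of a parameter set
#'
#' @param params an `mlp_params` object.
#' @return integer vector of widths, input dimension first.
#' @export
mlp_dims <- function(params) {
  c(ncol(params[[1]]$W), vapply(params, function(l) nrow(l$W), integer(1)))
}

#' Number of trainable parameters
#'
#' @param params an `mlp_params` object.
#' @return total count of weights plus biases.
#' @export
mlp_n_params <- function(params) {
  sum(vapply(params, function(l) length(l$W) + length(l$b), numeric(1)))
}

apply_activation <- function(z, activation) {
  switch(activation, relu = pmax(z, 0), linear = z,
         stop_validation("unknown activation: ", activation))
}

#' Forward pass through a feed-forward network
#'
#' Computes y = F(W x + b) layer by layer, with `relu(z) = max(0, z)` and
#' `linear(z) = z`. Input is batch-major: one sample per row.
#'
#' @param params an `mlp_params` object.
#' @param x numeric matrix (n_samples x input_dim) or vector (one sample).
#' @return matrix of activations at the output layer (n_samples x out_dim).
#' @export
mlp_forward <- function(params, x) {
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  if (ncol(x) != ncol(params[[1]]$W))
    stop_validation("input has ", ncol(x), " features; network expects ",
                    ncol(params[[1]]$W))
  a <- x
  for (layer in params) {
    z <- a %*% t(layer$W)
    z <- sweep(z, 2L, layer$b, "+")
    a <- apply_activation(z, layer$activation)
  }
  a
}

# Forward pass retaining per-layer activations for backpropagation.
forward_cached <- function(params, x) {
  acts <- vector("list", length(params) + 1L)
  pre <- vector("list", length(params))
  acts[[1]] <- x
  for (l in seq_along(params)) {
    z <- acts[[l]] %*% t(params[[l]]$W)
    z <- sweep(z, 2L, params[[l]]$b, "+")
    pre[[l]] <- z
    acts[[l + 1L]] <- apply_activation(z, params[[l]]$activation)
  }
  list(acts = acts, pre = pre)
}

# Backpropagate an output-side delta through a cached forward pass.
# Returns per-layer gradients plus the delta wrt the network input, so
# chains of networks (e.g., encoders feeding a prediction head) can be
# trained jointly.
mlp_backprop <- function(params, fc, delta) {
  grads <- vector("list", length(params))
  for (l in rev(seq_along(params))) {
    if (params[[l]]$activation == "relu")
      delta <- delta * (fc$pre[[l]] > 0)
    grads[[l]] <- list(W = t(delta) %*% fc$acts[[l]], b = colSums(delta))
    delta <- delta %*% params[[l]]$W
  }
  list(grads = grads, input_delta = delta)
}

# Gradient of mean((pred - y)^2) (mean over all n * d entries) wrt all
# weights and biases, by standard backpropagation.
mlp_gradients <- function(params, x, y) {
  fc <- forward_cached(params, x)
  n_out <- length(y)
  delta <- 2 * (fc$acts[[length(params) + 1L]] - y) / n_out
  mlp_backprop(params, fc, delta)$grads
}

mse_loss <- function(pred, y) mean((pred - y)^2)

adam_state_init <- function(params) {
  lapply(params, function(layer) list(
    mW = matrix(0, nrow(layer$W), ncol(layer$W)), vW = matrix(0, nrow(layer$W), ncol(layer$W)),
    mb = numeric(length(layer$b)), vb = numeric(length(layer$b))
  ))
}

adam_step <- function(params, grads, state, t, cfg) {
  b1 <- cfg$beta1; b2 <- cfg$beta2; lr <- cfg$learning_rate; eps <- cfg$adam_eps
  c1 <- 1 - b1^t; c2 <- 1 - b2^t
  for (l in seq_along(params)) {
    st <- state[[l]]; g <- grads[[l]]
    st$mW <- b1 * st$mW + (1 - b1) * g$W
    st$vW <- b2 * st$vW + (1 - b2) * g$W^2
    st$mb <- b1 * st$mb + (1 - b1) * g$b
    st$vb <- b2 * st$vb + (1 - b2) * g$b^2
    params[[l]]$W <- params[[l]]$W - lr * (st$mW / c1) / (sqrt(st$vW / c2) + eps)
    params[[l]]$b <- params[[l]]$b - lr * (st$mb / c1) / (sqrt(st$vb / c2) + eps)
    state[[l]] <- st
  }
  list(params = params, state = state)
}

#' Epoch at which early stopping halts for a given loss sequence
#'
#' Applies the package's early-stopping rule to a sequence of per-epoch
#' validation losses: any strict decrease below the best loss so far resets
#' the patience counter; training halts at the first epoch where the loss
#' has failed to improve for `patience` consecutive epochs. This is the
#' exact rule [train_mse()] uses, factored out so the stopping behavior can
#' be reasoned about (and tested) on scripted loss sequences.
#'
#' @param losses numeric vector of per-epoch validation losses.
#' @param patience number of consecutive non-improving epochs tolerated.
#' @return the 1-based stopping epoch, or `length(losses)` if the rule
#'   never fires.
#' @export
early_stop_epoch <- function(losses, patience) {
  best <- Inf; wait <- 0L
  for (e in seq_along(losses)) {
    if (losses[e] < best) {
      best <- losses[e]; wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= patience) return(e)
    }
  }
  length(losses)
}

#' Train a network by mini-batch Adam on mean squared error
#'
#' Minimizes `mean((forward(params, X) - Y)^2)` by mini-batch adaptive
#' moment (Adam) updates. The mini-batch order is reshuffled each epoch
#' from the configured seed, so runs are bit-reproducible given
#' (seed, batch_size). When a validation set and a patience are supplied,
#' training halts after the validation loss has failed to improve for
#' `patience` consecutive epochs; the validation set never contributes
#' gradients.
#'
#' @param params initial `mlp_params` (e.g., from [he_uniform_init()]).
#' @param X training inputs, one sample per row.
#' @param Y training targets, one sample per row.
#' @param cfg a [train_config()].
#' @param validation optional `list(X =, Y =)` held-out set used only for
#'   early stopping and loss history.
#' @return list with `params` (trained), and `history`: per-epoch
#'   `train_loss`, `val_loss` (or `NULL`), and `stopped_epoch`.
#' @export
train_mse <- function(params, X, Y, cfg = train_config(), validation = NULL) {
  if (is.vector(Y)) Y <- matrix(Y, ncol = 1)
  if (is.vector(X)) X <- matrix(X, ncol = 1)
  if (nrow(X) != nrow(Y)) stop_validation("X and Y row counts differ")
  if (any(!is.finite(X)) || any(!is.finite(Y)))
    stop_validation("training data contain non-finite values")
  if (!is.null(validation)) {
    if (any(!is.finite(validation$X)) || any(!is.finite(validation$Y)))
      stop_validation("validation data contain non-finite values")
  }
  n <- nrow(X)
  train_loss <- numeric(0); val_loss <- numeric(0)
  stopped_epoch <- 0L
  if (cfg$max_epochs < 1)
    return(list(params = params,
                history = list(train_loss = train_loss, val_loss = NULL,
                               stopped_epoch = 0L)))
  state <- adam_state_init(params)
  step <- 0L
  best_val <- Inf; wait <- 0L; best_params <- params
  set.seed(cfg$seed)
  for (epoch in seq_len(cfg$max_epochs)) {
    ord <- sample.int(n)
    for (start in seq(1L, n, by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
      grads <- mlp_gradients(params, X[idx, , drop = FALSE], Y[idx, , drop = FALSE])
      step <- step + 1L
      upd <- adam_step(params, grads, state, step, cfg)
      params <- upd$params; state <- upd$state
    }
    tl <- mse_loss(mlp_forward(params, X), Y)
    if (!is.finite(tl))
      stop_numerical("training loss became non-finite at epoch ", epoch)
    train_loss <- c(train_loss, tl)
    stopped_epoch <- epoch
    if (!is.null(validation)) {
      vl <- mse_loss(mlp_forward(params, validation$X), validation$Y)
      val_loss <- c(val_loss, vl)
      if (vl < best_val) {
        best_val <- vl; wait <- 0L
        if (cfg$restore_best) best_params <- params
      } else {
        wait <- wait + 1L
        if (!is.null(cfg$patience) && wait >= cfg$patience) break
      }
    }
  }
  if (cfg$restore_best && !is.null(validation)) params <- best_params
  list(params = params,
       history = list(train_loss = train_loss,
                      val_loss = if (is.null(validation)) NULL else val_loss,
                      stopped_epoch = stopped_epoch))
}

#' Save a parameter archive
#'
#' Writes the named weight/bias arrays together with a manifest of layer
#' specifications (widths and activation tags) as a single archive; the
#' round-trip through [load_mlp()] is bit-exact.
#'
#' @param params an `mlp_params` object (or any model object built on them).
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
save_mlp <- function(params, path) {
  manifest <- if (inherits(params, "mlp_params"))
    list(dims = mlp_dims(params),
         activations = vapply(params, function(l) l$activation, character(1)))
  else list(class = class(params))
  saveRDS(list(manifest = manifest, params = params,
               package_version = as.character(utils::packageVersion("drtransfer"))),
          path)
  invisible(path)
}

#' Load a parameter archive written by [save_mlp()]
#'
#' @param path archive file path.
#' @return the stored parameter object.
#' @export
load_mlp <- function(path) {
  if (!file.exists(path)) stop_validation("model archive not found: ", path)
  readRDS(path)$params
}
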