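# Symmetric autoencoder pre-training on a large omics corpus. The encoder
# compresses an input profile through three widths down to a bottleneck;
# the decoder mirrors the widths back up to a linear reconstruction layer.
# Architecture is selected by an exhaustive grid (widths x batch size),
# each candidate screened for a few epochs, the winner refit longer.

#' The default architecture search grid
#'
#' Candidate widths for the three encoder layers, candidate batch sizes,
#' and the screening/refit epoch budgets. The default grid enumerates
#' 3 x 3 x 3 x 2 = 54 candidates; desk-scale runs pass a reduced grid.
#'
#' @param layer1,layer2,bottleneck candidate widths per encoder layer.
#' @param batch_size candidate mini-batch sizes.
#' @param screen_epochs epochs per screening run (default 20).
#' @param refit_epochs epochs for the final refit of the winner (default 100).
#' @return a list of class `search_grid`.
#' @export
search_grid <- function(layer1 = c(4096, 2048, 1024),
                        layer2 = c(512, 256, 128),
                        bottleneck = c(64, 32, 16),
                        batch_size = c(128, 64),
                        screen_epochs = 20, refit_epochs = 100) {
  if (!length(layer1) || !length(layer2) || !length(bottleneck) || !length(batch_size))
    stop_validation("all candidate lists of the search grid must be non-empty")
  structure(list(layer1 = layer1, layer2 = layer2, bottleneck = bottleneck,
                 batch_size = batch_size,
                 screen_epochs = as.integer(screen_epochs),
                 refit_epochs = as.integer(refit_epochs)),
            class = "search_grid")
}

#' Enumerate all candidates of a search grid
#'
#' @param grid a [search_grid()].
#' @return data.frame with one row per (layer1, layer2, bottleneck,
#'   batch_size) combination.
#' @export
grid_candidates <- function(grid) {
  expand.grid(layer1 = grid$layer1, layer2 = grid$layer2,
              bottleneck = grid$bottleneck, batch_size = grid$batch_size,
              KEEP.OUT.ATTRS = FALSE)
}

#' Build a symmetric autoencoder
#'
#' The full network chains
#' `input -> w1 -> w2 -> bottleneck -> w2 -> w1 -> input`, rectifier
#' activations throughout except a linear reconstruction output, with
#' He-uniform initialization.
#'
#' @param input_dim number of input features.
#' @param widths length-3 vector `(layer1, layer2, bottleneck)`.
#' @param seed integer seed for initialization.
#' @return an `mlp_params` object with attribute `n_encoder_layers = 3`.
#' @export
build_autoencoder <- function(input_dim, widths, seed = 1L) {
  if (length(widths) != 3 || any(widths < 1))
    stop_validation("widths must be 3 positive layer sizes")
  if (widths[3] >= input_dim)
    warning("bottleneck width >= input dimension: no compression")
  dims <- c(input_dim, widths, rev(widths[-3]), input_dim)
  params <- he_uniform_init(dims, seed = seed)
  attr(params, "n_encoder_layers") <- 3L
  params
}

#' Extract the encoder half of an autoencoder
#'
#' @param ae an autoencoder from [build_autoencoder()] (possibly trained).
#' @return an `mlp_params` object mapping input to bottleneck activations
#'   (rectified).
#' @export
encoder_half <- function(ae) {
  n_enc <- attr(ae, "n_encoder_layers")
  if (is.null(n_enc)) stop_validation("not an autoencoder parameter set")
  enc <- unclass(ae)[seq_len(n_enc)]
  # the bottleneck keeps its rectifier: downstream networks consume the
  # same activations the decoder saw
  structure(enc, class = "mlp_params")
}

#' Encode a batch of profiles at the bottleneck
#'
#' @param encoder an encoder `mlp_params` (from [encoder_half()] or
#'   [grid_search_autoencoder()]).
#' @param X feature x sample matrix (package convention) to encode.
#' @return bottleneck x sample matrix of activations.
#' @export
encode <- function(encoder, X) {
  t(mlp_forward(encoder, t(X)))
}

# Train one autoencoder on samples-in-rows data; returns params + history.
train_autoencoder_once <- function(Xs, widths, batch_size, epochs, seed,
                                   holdout_idx = NULL, learning_rate = 1e-3) {
  ae <- build_autoencoder(ncol(Xs), widths, seed = seed)
  cfg <- train_config(learning_rate = learning_rate, batch_size = batch_size,
                      max_epochs = epochs, seed = derive_seed(seed, 17L))
  if (is.null(holdout_idx)) {
    fit <- train_mse(ae, Xs, Xs, cfg)
    loss <- tail(fit$history$train_loss, 1)
  } else {
    Xtr <- Xs[-holdout_idx, , drop = FALSE]
    Xho <- Xs[holdout_idx, , drop = FALSE]
    fit <- train_mse(ae, Xtr, Xtr, cfg,
                     validation = list(X = Xho, Y = Xho))
    loss <- tail(fit$history$val_loss, 1)
  }
  attr(fit$params, "n_encoder_layers") <- 3L
  list(params = fit$params, loss = loss, history = fit$history)
}

#' Grid search over autoencoder architectures with screen-and-refit
#'
#' Every grid candidate is trained for `screen_epochs` epochs; the
#' candidate with the lowest reconstruction MSE (on a held-out corpus
#' slice by default) wins, with ties broken toward the smaller parameter
#' count and then lexicographic widths. The winner is re-trained from a
#' fresh seed-derived initialization for `refit_epochs` epochs and its
#' encoder half is returned.
#'
#' @param corpus feature x sample matrix of the pre-training corpus.
#' @param grid a [search_grid()].
#' @param seed integer seed governing the held-out split, every candidate
#'   initialization and the refit.
#' @param holdout_fraction fraction of corpus samples held out for the
#'   selection criterion (default 0.1); set `select_on = "train"` to score
#'   candidates on their training reconstruction loss instead.
#' @param select_on `"holdout"` (default) or `"train"`.
#' @param learning_rate Adam step size used for every run.
#' @return list with `best` (the winning grid row), `encoder` (refit
#'   encoder `mlp_params`), `autoencoder` (full refit network), and
#'   `log` (data.frame of all candidates with their screened losses).
#' @export
grid_search_autoencoder <- function(corpus, grid = search_grid(), seed = 1L,
                                    holdout_fraction = 0.1,
                                    select_on = c("holdout", "train"),
                                    learning_rate = 1e-3) {
  select_on <- match.arg(select_on)
  check_feature_matrix(corpus, "corpus")
  if (ncol(corpus) < 2) stop_validation("corpus needs at least 2 samples")
  cand <- grid_candidates(grid)
  if (!nrow(cand)) stop_validation("empty search grid")
  Xs <- t(corpus)
  holdout_idx <- NULL
  if (select_on == "holdout") {
    set.seed(derive_seed(seed, 1L))
    n_ho <- max(1L, round(holdout_fraction * nrow(Xs)))
    holdout_idx <- sort(sample.int(nrow(Xs), n_ho))
  }
  cand$loss <- NA_real_
  cand$n_params <- NA_real_
  for (i in seq_len(nrow(cand))) {
    widths <- as.numeric(cand[i, c("layer1", "layer2", "bottleneck")])
    run <- train_autoencoder_once(Xs, widths, cand$batch_size[i],
                                  grid$screen_epochs,
                                  seed = derive_seed(seed, 100L + i),
                                  holdout_idx = holdout_idx,
                                  learning_rate = learning_rate)
    cand$loss[i] <- run$loss
    cand$n_params[i] <- mlp_n_params(run$params)
  }
  ord <- order(cand$loss, cand$n_params, cand$layer1, cand$layer2,
               cand$bottleneck, cand$batch_size)
  best <- cand[ord[1], , drop = FALSE]
  refit <- train_autoencoder_once(
    Xs, as.numeric(best[c("layer1", "layer2", "bottleneck")]),
    best$batch_size, grid$refit_epochs,
    seed = derive_seed(seed, 997L), holdout_idx = holdout_idx,
    learning_rate = learning_rate)
  list(best = best, encoder = encoder_half(refit$params),
       autoencoder = refit$params, refit_loss = refit$loss, log = cand)
}
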