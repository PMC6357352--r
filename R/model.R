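# The complete prediction network: a mutation encoder and an expression
# encoder (pre-trained on the tumor corpus, trainable thereafter) feeding
# a prediction head P with rectifier hidden layers and a linear output of
# one neuron per drug. Baselines swap the encoders for random
# initialization, fixed PCA projections, or drop one omics branch.

#' Assemble the joint response-prediction model
#'
#' Encoders carry their (pre-trained) parameters in and remain trainable;
#' the prediction head is freshly He-uniform initialized. The head's first
#' fan-in equals the summed encoder output widths (64 + 64 at paper scale).
#'
#' @param menc mutation encoder: an `mlp_params` (trainable) or a
#'   `pca_encoder` (fixed projection), or `NULL` for an expression-only
#'   model.
#' @param eenc expression encoder, same choices; `NULL` for mutation-only.
#' @param n_drugs width of the linear output layer (one neuron per drug).
#' @param head_widths hidden widths of the prediction head
#'   (default `c(128, 128, 128)`).
#' @param seed seed for the head initialization.
#' @param mutation_genes,expression_genes,drug_ids optional identifier
#'   vectors recorded for input validation and output labeling.
#' @return an object of class `response_model`.
#' @export
assemble_model <- function(menc, eenc, n_drugs, head_widths = c(128, 128, 128),
                           seed = 1L, mutation_genes = NULL,
                           expression_genes = NULL, drug_ids = NULL) {
  if (is.null(menc) && is.null(eenc))
    stop_validation("at least one encoder is required")
  if (n_drugs < 1) stop_validation("n_drugs must be >= 1")
  concat_width <- encoder_out_width(menc) + encoder_out_width(eenc)
  head <- he_uniform_init(c(concat_width, head_widths, n_drugs),
                          seed = derive_seed(seed, 31L))
  structure(list(menc = menc, eenc = eenc, head = head,
                 n_drugs = as.integer(n_drugs),
                 mutation_genes = mutation_genes,
                 expression_genes = expression_genes,
                 drug_ids = drug_ids),
            class = "response_model")
}

encoder_out_width <- function(enc) {
  if (is.null(enc)) return(0L)
  if (inherits(enc, "mlp_params")) return(tail(mlp_dims(enc), 1))
  if (inherits(enc, "pca_encoder")) return(ncol(enc$rotation))
  stop_validation("encoder must be mlp_params, pca_encoder, or NULL")
}

encoder_in_width <- function(enc) {
  if (is.null(enc)) return(0L)
  if (inherits(enc, "mlp_params")) return(mlp_dims(enc)[1])
  nrow(enc$rotation)
}

#' Total trainable + fixed parameter count of a response model
#'
#' @param model a `response_model`.
#' @return sum of parameter counts over both encoders and the head
#'   (a PCA encoder contributes its center + loadings).
#' @export
model_n_params <- function(model) {
  count1 <- function(enc) {
    if (is.null(enc)) 0
    else if (inherits(enc, "mlp_params")) mlp_n_params(enc)
    else length(enc$center) + length(enc$rotation)
  }
  count1(model$menc) + count1(model$eenc) + mlp_n_params(model$head)
}

# Encoder forward on samples-in-rows input; PCA encoders are fixed affine
# projections.
encoder_forward_rows <- function(enc, Xs) {
  if (inherits(enc, "mlp_params")) mlp_forward(enc, Xs)
  else sweep(Xs, 2L, enc$center, "-") %*% enc$rotation
}

#' Random train/validation/test split over samples
#'
#' Validation and test sizes are `round(fraction * n)`; the remainder goes
#' to training. Deterministic given the seed.
#'
#' @param sample_ids character vector of sample identifiers.
#' @param fractions length-3 vector of train/validation/test fractions
#'   summing to 1 (default `c(0.8, 0.1, 0.1)`).
#' @param seed integer seed.
#' @return list of class `split_assignment` with character vectors
#'   `train`, `validation`, `test`.
#' @export
split_samples <- function(sample_ids, fractions = c(0.8, 0.1, 0.1), seed = 1L) {
  if (abs(sum(fractions) - 1) > 1e-8)
    stop_validation("fractions must sum to 1")
  n <- length(sample_ids)
  n_val <- round(fractions[2] * n)
  n_test <- round(fractions[3] * n)
  n_train <- n - n_val - n_test
  if (min(n_train, n_val, n_test) < 1)
    stop_validation("split produced an empty set (n = ", n, ")")
  set.seed(as.integer(seed))
  ord <- sample(sample_ids)
  structure(list(train = ord[seq_len(n_train)],
                 validation = ord[n_train + seq_len(n_val)],
                 test = ord[n_train + n_val + seq_len(n_test)]),
            class = "split_assignment")
}

check_split <- function(split, sample_ids) {
  all_ids <- c(split$train, split$validation, split$test)
  if (anyDuplicated(all_ids))
    stop_validation("split sets overlap: ",
                    paste(head(all_ids[duplicated(all_ids)], 5), collapse = ", "))
  if (!setequal(all_ids, sample_ids))
    stop_validation("split does not cover the sample set")
  invisible(split)
}

# Forward pass of the joint model on samples-in-rows omics blocks; caches
# everything needed for joint backprop.
model_forward_cached <- function(model, Ms, Es) {
  branch <- function(enc, Xs) {
    if (is.null(enc)) return(NULL)
    if (inherits(enc, "mlp_params")) forward_cached(enc, Xs)
    else list(acts = list(Xs, encoder_forward_rows(enc, Xs)), pre = NULL)
  }
  bm <- branch(model$menc, Ms)
  be <- branch(model$eenc, Es)
  concat <- cbind(if (!is.null(bm)) bm$acts[[length(bm$acts)]],
                  if (!is.null(be)) be$acts[[length(be$acts)]])
  fh <- forward_cached(model$head, concat)
  list(bm = bm, be = be, concat = concat, head = fh,
       pred = fh$acts[[length(model$head) + 1L]])
}

# One joint gradient evaluation; returns grads for head and each trainable
# encoder branch.
model_gradients <- function(model, Ms, Es, Y) {
  fc <- model_forward_cached(model, Ms, Es)
  delta <- 2 * (fc$pred - Y) / length(Y)
  bp_head <- mlp_backprop(model$head, fc$head, delta)
  wm <- encoder_out_width(model$menc)
  grads <- list(head = bp_head$grads, menc = NULL, eenc = NULL)
  if (inherits(model$menc, "mlp_params")) {
    dm <- bp_head$input_delta[, seq_len(wm), drop = FALSE]
    grads$menc <- mlp_backprop(model$menc, fc$bm, dm)$grads
  }
  if (inherits(model$eenc, "mlp_params")) {
    de <- bp_head$input_delta[, wm + seq_len(encoder_out_width(model$eenc)),
                              drop = FALSE]
    grads$eenc <- mlp_backprop(model$eenc, fc$be, de)$grads
  }
  grads
}

#' Train the joint model end-to-end
#'
#' Trains all trainable components (both encoders and the head) by
#' mini-batch Adam on the mean squared error of predicted vs observed
#' log-IC50 over the training samples. The validation split is used only
#' for early stopping; the report is computed on the test split.
#'
#' @param model a `response_model` from [assemble_model()].
#' @param M gene x sample binary mutation matrix (`NULL` for
#'   expression-only models).
#' @param E gene x sample expression matrix (`NULL` for mutation-only).
#' @param IC drug x sample response matrix, fully imputed (no `NA`).
#' @param split a `split_assignment` over the shared samples.
#' @param cfg a [train_config()]; the default uses patience 3, matching
#'   the pipeline's early-stopping convention.
#' @return list with `model` (trained), `metrics` (a [compute_metrics()]
#'   report on the test split plus `epochs`), and `history`.
#' @export
train_response_model <- function(model, M, E, IC, split,
                                 cfg = train_config(patience = 3)) {
  sample_ids <- colnames(IC)
  check_split(split, sample_ids)
  if (anyNA(IC)) stop_validation("IC must be fully imputed before training")
  if (!is.null(model$menc) && is.null(M)) stop_validation("model needs mutation data")
  if (!is.null(model$eenc) && is.null(E)) stop_validation("model needs expression data")
  for (X in list(M, E)) if (!is.null(X) && !identical(colnames(X), sample_ids))
    stop_validation("omics matrices and IC must share ordered sample ids")

  take <- function(X, ids) if (is.null(X)) NULL else t(X[, ids, drop = FALSE])
  sets <- lapply(list(train = split$train, validation = split$validation,
                      test = split$test),
                 function(ids) list(M = take(M, ids), E = take(E, ids),
                                    Y = t(IC[, ids, drop = FALSE])))
  n <- length(split$train)
  state <- list(head = adam_state_init(model$head),
                menc = if (inherits(model$menc, "mlp_params")) adam_state_init(model$menc),
                eenc = if (inherits(model$eenc, "mlp_params")) adam_state_init(model$eenc))
  step <- 0L
  best_val <- Inf; wait <- 0L
  train_loss <- numeric(0); val_loss <- numeric(0); stopped <- 0L
  set.seed(cfg$seed)
  for (epoch in seq_len(cfg$max_epochs)) {
    ord <- sample.int(n)
    for (start in seq(1L, n, by = cfg$batch_size)) {
      idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
      sub <- function(X) if (is.null(X)) NULL else X[idx, , drop = FALSE]
      g <- model_gradients(model, sub(sets$train$M), sub(sets$train$E),
                           sets$train$Y[idx, , drop = FALSE])
      step <- step + 1L
      upd <- adam_step(model$head, g$head, state$head, step, cfg)
      model$head <- upd$params; state$head <- upd$state
      if (!is.null(g$menc)) {
        upd <- adam_step(model$menc, g$menc, state$menc, step, cfg)
        model$menc <- structure(upd$params, class = "mlp_params")
        state$menc <- upd$state
      }
      if (!is.null(g$eenc)) {
        upd <- adam_step(model$eenc, g$eenc, state$eenc, step, cfg)
        model$eenc <- structure(upd$params, class = "mlp_params")
        state$eenc <- upd$state
      }
    }
    loss_on <- function(set) mse_loss(model_forward_cached(model, set$M, set$E)$pred, set$Y)
    tl <- loss_on(sets$train)
    if (!is.finite(tl)) stop_numerical("training loss non-finite at epoch ", epoch)
    train_loss <- c(train_loss, tl)
    vl <- loss_on(sets$validation)
    val_loss <- c(val_loss, vl)
    stopped <- epoch
    if (vl < best_val) { best_val <- vl; wait <- 0L }
    else {
      wait <- wait + 1L
      if (!is.null(cfg$patience) && wait >= cfg$patience) break
    }
  }
  pred_test <- t(model_forward_cached(model, sets$test$M, sets$test$E)$pred)
  dimnames(pred_test) <- list(rownames(IC), split$test)
  metrics <- compute_metrics(pred_test, IC[, split$test, drop = FALSE])
  metrics$epochs <- stopped
  list(model = model, metrics = metrics,
       history = list(train_loss = train_loss, val_loss = val_loss,
                      stopped_epoch = stopped))
}

#' Predict the drug-response panel for new samples
#'
#' A high predicted log-IC50 marks an adverse (resistant) response; low
#' values mark sensitivity.
#'
#' @param model a (trained) `response_model`.
#' @param M,E gene x sample matrices matching the model's input
#'   dimensions; pass `NULL` for an absent branch.
#' @return drug x sample matrix of predicted log-IC50, no missing entries.
#' @export
predict_response <- function(model, M = NULL, E = NULL) {
  check_model_inputs(model, M, E)
  n <- if (!is.null(M)) ncol(M) else ncol(E)
  sample_ids <- if (!is.null(M)) colnames(M) else colnames(E)
  pred <- t(model_forward_cached(model,
                                 if (is.null(model$menc)) NULL else t(M),
                                 if (is.null(model$eenc)) NULL else t(E))$pred)
  rownames(pred) <- model$drug_ids %||% paste0("drug_", seq_len(model$n_drugs))
  colnames(pred) <- sample_ids
  pred
}

`%||%` <- function(a, b) if (is.null(a)) b else a

check_model_inputs <- function(model, M, E) {
  check1 <- function(enc, X, genes, what) {
    if (is.null(enc)) return(invisible())
    if (is.null(X)) stop_validation("model requires ", what, " input")
    if (!is.null(genes)) {
      missing_genes <- setdiff(genes, rownames(X))
      if (length(missing_genes))
        stop_validation(what, " input is missing genes: ",
                        paste(head(missing_genes, 10), collapse = ", "))
    }
    if (nrow(X) != encoder_in_width(enc))
      stop_validation(what, " input has ", nrow(X), " genes; model expects ",
                      encoder_in_width(enc))
  }
  check1(model$menc, M, model$mutation_genes, "mutation")
  check1(model$eenc, E, model$expression_genes, "expression")
  invisible()
}

#' Prediction performance metrics
#'
#' Overall MSE across all (drug, sample) cells, plus per-sample Pearson and
#' Spearman correlations computed across the drug panel (how well each
#' sample's drug ranking is reproduced). Samples whose true or predicted
#' vector has zero variance get `NA` correlations with a warning.
#'
#' @param pred,truth aligned drug x sample matrices.
#' @return list of class `metrics_report`: `mse`, `pearson` (per sample),
#'   `spearman` (per sample).
#' @export
compute_metrics <- function(pred, truth) {
  if (!all(dim(pred) == dim(truth)))
    stop_validation("pred and truth dimensions differ")
  mse <- mean((pred - truth)^2)
  n <- ncol(pred)
  pear <- numeric(n); spear <- numeric(n)
  degenerate <- FALSE
  for (s in seq_len(n)) {
    if (stats::sd(pred[, s]) == 0 || stats::sd(truth[, s]) == 0) {
      pear[s] <- NA_real_; spear[s] <- NA_real_; degenerate <- TRUE
    } else {
      pear[s] <- stats::cor(pred[, s], truth[, s], method = "pearson")
      spear[s] <- stats::cor(pred[, s], truth[, s], method = "spearman")
    }
  }
  if (degenerate)
    warning("zero-variance sample vector(s): correlation reported as NA")
  names(pear) <- names(spear) <- colnames(pred)
  structure(list(mse = mse, pearson = pear, spearman = spear),
            class = "metrics_report")
}

#' Fit a PCA projection on training samples
#'
#' Centering vector and top-k loadings are fitted on the training samples
#' only; the transform projects centered profiles onto the loadings. Used
#' as the fixed dimension-reduction baseline in place of a learned encoder.
#'
#' @param X_train feature x sample matrix (training split only).
#' @param n_components number of leading components (default 64).
#' @return object of class `pca_encoder` with `center` (features) and
#'   `rotation` (features x k), plus `sdev`.
#' @export
pca_encoder <- function(X_train, n_components = 64) {
  if (n_components > min(dim(X_train)))
    stop_validation("n_components exceeds matrix rank bound")
  pc <- stats::prcomp(t(X_train), center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pc$rotation))
  if (k < n_components)
    stop_validation("n_components (", n_components, ") exceeds available rank (", k, ")")
  structure(list(center = pc$center,
                 rotation = pc$rotation[, seq_len(k), drop = FALSE],
                 sdev = pc$sdev),
            class = "pca_encoder")
}

#' Project samples onto a fitted PCA encoder
#'
#' @param pe a [pca_encoder()].
#' @param X feature x sample matrix.
#' @return components x sample score matrix.
#' @export
pca_transform <- function(pe, X) {
  t(encoder_forward_rows(pe, t(X)))
}

#' Benchmark the transfer model against its baselines
#'
#' Runs `n_iter` iterations; in each, samples are randomly re-assigned to
#' train/validation/test (80/10/10 by default) and every requested model is
#' trained and evaluated on the identical split:
#' \describe{
#'   \item{pretrained}{the full model, encoders initialized from pre-training}
#'   \item{random_init}{identical architecture, He-uniform encoders}
#'   \item{pca_encoders}{each encoder replaced by a fixed top-k PCA projection}
#'   \item{eenc_only / menc_only}{single-omics variants}
#'   \item{linear_regression}{multivariate least squares on the merged PCs,
#'     all drugs at once}
#'   \item{svm_per_drug}{one radial-kernel support-vector regressor per drug
#'     on the merged PCs}
#' }
#'
#' @param M,E,IC aligned mutation, expression and (imputed) response
#'   matrices.
#' @param menc,eenc pre-trained encoders (`mlp_params`) for the
#'   `pretrained` model and single-omics variants.
#' @param n_iter number of resampling iterations (default 100).
#' @param seed global seed; iteration i uses a derived stream.
#' @param n_components PCA components per omics for the PCA-based models
#'   (default 64; reduce at desk scale).
#' @param head_widths prediction-head widths.
#' @param cfg a [train_config()] applied to every network.
#' @param models subset of model names to run.
#' @param fractions split fractions.
#' @return object of class `benchmark_table`: `per_iteration` data.frame
#'   (model, iteration, mse, epochs) and `summary` with per-model median
#'   MSE and median epochs.
#' @export
run_benchmark <- function(M, E, IC, menc, eenc, n_iter = 100, seed = 1L,
                          n_components = 64, head_widths = c(128, 128, 128),
                          cfg = train_config(patience = 3),
                          models = c("pretrained", "random_init", "pca_encoders",
                                     "eenc_only", "menc_only",
                                     "linear_regression", "svm_per_drug"),
                          fractions = c(0.8, 0.1, 0.1)) {
  if (n_iter < 1) stop_validation("n_iter must be >= 1")
  models <- match.arg(models, several.ok = TRUE)
  sample_ids <- colnames(IC)
  D <- nrow(IC)
  rows <- list()
  for (it in seq_len(n_iter)) {
    it_seed <- derive_seed(seed, 1000L + it)
    split <- split_samples(sample_ids, fractions, seed = it_seed)
    cfg_it <- cfg; cfg_it$seed <- derive_seed(it_seed, 7L)
    run_nn <- function(model) {
      fit <- train_response_model(model, M, E, IC, split, cfg_it)
      c(mse = fit$metrics$mse, epochs = fit$metrics$epochs)
    }
    need_pcs <- any(c("pca_encoders", "linear_regression", "svm_per_drug") %in% models)
    if (need_pcs) {
      pm <- pca_encoder(M[, split$train, drop = FALSE], n_components)
      pe <- pca_encoder(E[, split$train, drop = FALSE], n_components)
      merged <- function(ids) cbind(t(pca_transform(pm, M[, ids, drop = FALSE])),
                                    t(pca_transform(pe, E[, ids, drop = FALSE])))
      Xtr <- merged(split$train); Xte <- merged(split$test)
      Ytr <- t(IC[, split$train, drop = FALSE])
      Yte <- t(IC[, split$test, drop = FALSE])
    }
    for (mod in models) {
      res <- switch(
        mod,
        pretrained = run_nn(assemble_model(menc, eenc, D, head_widths,
                                           seed = derive_seed(it_seed, 11L))),
        random_init = {
          m0 <- he_uniform_init(mlp_dims(menc),
                                activations = vapply(menc, `[[`, "", "activation"),
                                seed = derive_seed(it_seed, 12L))
          e0 <- he_uniform_init(mlp_dims(eenc),
                                activations = vapply(eenc, `[[`, "", "activation"),
                                seed = derive_seed(it_seed, 13L))
          run_nn(assemble_model(m0, e0, D, head_widths,
                                seed = derive_seed(it_seed, 11L)))
        },
        pca_encoders = run_nn(assemble_model(
          pca_encoder(M[, split$train, drop = FALSE], n_components),
          pca_encoder(E[, split$train, drop = FALSE], n_components),
          D, head_widths, seed = derive_seed(it_seed, 11L))),
        eenc_only = run_nn(assemble_model(NULL, eenc, D, head_widths,
                                          seed = derive_seed(it_seed, 11L))),
        menc_only = run_nn(assemble_model(menc, NULL, D, head_widths,
                                          seed = derive_seed(it_seed, 11L))),
        linear_regression = {
          fit <- stats::lm.fit(cbind(1, Xtr), Ytr)
          pred <- cbind(1, Xte) %*% fit$coefficients
          c(mse = mean((pred - Yte)^2), epochs = NA_real_)
        },
        svm_per_drug = {
          pred <- vapply(seq_len(D), function(d) {
            sv <- e1071::svm(x = Xtr, y = Ytr[, d], kernel = "radial")
            as.numeric(stats::predict(sv, Xte))
          }, numeric(nrow(Xte)))
          c(mse = mean((pred - Yte)^2), epochs = NA_real_)
        })
      rows[[length(rows) + 1L]] <-
        data.frame(model = mod, iteration = it, mse = res[["mse"]],
                   epochs = res[["epochs"]])
    }
  }
  per_iteration <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(per_iteration, per_iteration$model), function(d)
    data.frame(model = d$model[1],
               median_mse = stats::median(d$mse),
               median_epochs = stats::median(d$epochs))))
  summ <- summ[match(models, summ$model), , drop = FALSE]
  rownames(summ) <- NULL
  structure(list(per_iteration = per_iteration, summary = summ),
            class = "benchmark_table")
}
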