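tiny_encoders <- function(gm = 20, ge = 30, b = 4, seed = 1) {
  list(menc = he_uniform_init(c(gm, 8, 6, b), rep("relu", 3), seed = seed),
       eenc = he_uniform_init(c(ge, 8, 6, b), rep("relu", 3), seed = seed + 1))
}

tiny_data <- function(gm = 20, ge = 30, D = 6, n = 40, seed = 2) {
  list(M = rand_matrix(gm, n, seed = seed,
                       rfun = function(k) rbinom(k, 1, 0.2), rprefix = "mg"),
       E = abs(rand_matrix(ge, n, seed = seed + 1, rprefix = "eg")),
       IC = rand_matrix(D, n, seed = seed + 2, rprefix = "drug_"))
}

test_that("assembly transfers encoder parameters and sizes the head correctly", {
  enc <- tiny_encoders()
  model <- assemble_model(enc$menc, enc$eenc, n_drugs = 6,
                          head_widths = c(10, 10, 10), seed = 3)
  # transfer is a copy: encoder params identical to their archives
  expect_identical(unclass(model$menc), unclass(enc$menc))
  expect_identical(unclass(model$eenc), unclass(enc$eenc))
  # head first fan-in = sum of bottleneck widths; output linear of D neurons
  expect_equal(mlp_dims(model$head), c(8, 10, 10, 10, 6))
  expect_identical(model$head[[length(model$head)]]$activation, "linear")
  # total parameter count is the closed-form sum over all three networks
  count_chain <- function(dims) sum(dims[-length(dims)] * dims[-1] + dims[-1])
  expect_equal(model_n_params(model),
               count_chain(c(20, 8, 6, 4)) + count_chain(c(30, 8, 6, 4)) +
                 count_chain(c(8, 10, 10, 10, 6)))
  expect_error(assemble_model(enc$menc, enc$eenc, n_drugs = 0),
               class = "drt_validation_error")
  expect_error(assemble_model(NULL, NULL, 5), class = "drt_validation_error")
})

test_that("sample splits have the stated sizes and are seed-deterministic", {
  ids <- paste0("s", 1:10)
  sp <- split_samples(ids, seed = 4)
  expect_identical(lengths(sp[c("train", "validation", "test")]),
                   c(train = 8L, validation = 1L, test = 1L))
  expect_setequal(unlist(sp), ids)
  expect_identical(split_samples(ids, seed = 4), sp)
  expect_false(identical(split_samples(ids, seed = 5), sp))
  # 622 samples: round(0.1 * 622) = 62 validation and test cells
  sp622 <- split_samples(paste0("c", 1:622), seed = 6)
  expect_true(length(sp622$test) %in% c(62L, 63L))
  expect_identical(length(sp622$train) + length(sp622$validation) +
                     length(sp622$test), 622L)
  expect_error(split_samples(paste0("s", 1:3), c(0.98, 0.01, 0.01)),
               "empty", class = "drt_validation_error")
})

test_that("an all-constant response panel is learned through the bias path", {
  dat <- tiny_data()
  dat$IC[] <- 1.7
  enc <- tiny_encoders()
  model <- assemble_model(enc$menc, enc$eenc, nrow(dat$IC),
                          head_widths = c(8, 8, 8), seed = 5)
  sp <- split_samples(colnames(dat$IC), seed = 5)
  fit <- train_response_model(model, dat$M, dat$E, dat$IC, sp,
                              train_config(patience = NULL, max_epochs = 150,
                                           learning_rate = 1e-2, batch_size = 16,
                                           seed = 6))
  # test MSE beats the zero predictor (variance around 0 = 1.7^2)
  expect_lt(fit$metrics$mse, 1.7^2)
  expect_lt(fit$metrics$mse, 0.05)
})

test_that("prediction equals the independent composition of encoders and head", {
  dat <- tiny_data()
  enc <- tiny_encoders()
  model <- assemble_model(enc$menc, enc$eenc, nrow(dat$IC), c(8, 8, 8),
                          seed = 7, drug_ids = rownames(dat$IC))
  pred <- predict_response(model, dat$M, dat$E)
  expect_identical(dim(pred), dim(dat$IC))
  expect_false(anyNA(pred))
  # independent recomputation: forward(P, concat(encode(menc), encode(eenc)))
  concat <- rbind(encode(model$menc, dat$M), encode(model$eenc, dat$E))
  want <- t(mlp_forward(model$head, t(concat)))
  expect_lt(max(abs(pred - want)), 1e-12)
  # identical inputs give identical prediction vectors
  M2 <- dat$M; E2 <- dat$E
  M2[, 2] <- M2[, 1]; E2[, 2] <- E2[, 1]
  pred2 <- predict_response(model, M2, E2)
  expect_identical(unname(pred2[, 1]), unname(pred2[, 2]))
  expect_error(predict_response(model, dat$M[1:5, ], dat$E), "expects",
               class = "drt_validation_error")
})

test_that("metrics match textbook formulas and behave on anchor cases", {
  truth <- rand_matrix(5, 4, seed = 8, rprefix = "d")
  expect_equal(compute_metrics(truth, truth)$mse, 0)
  expect_equal(unname(compute_metrics(truth, truth)$pearson), rep(1, 4))
  expect_equal(unname(compute_metrics(truth, truth)$spearman), rep(1, 4))
  # a rank-reversing monotone transform gives Spearman -1 per sample
  rev_pred <- -truth^3
  expect_equal(unname(compute_metrics(rev_pred, truth)$spearman), rep(-1, 4))

  pred <- rand_matrix(5, 4, seed = 9, rprefix = "d")
  got <- compute_metrics(pred, truth)
  # direct-formula recomputation
  expect_lt(abs(got$mse - sum((pred - truth)^2) / 20), 1e-12)
  for (s in 1:4) {
    x <- pred[, s]; y <- truth[, s]
    pear <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_lt(abs(got$pearson[s] - pear), 1e-12)
    rx <- rank(x); ry <- rank(y)
    spear <- sum((rx - mean(rx)) * (ry - mean(ry))) /
      sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
    expect_lt(abs(got$spearman[s] - spear), 1e-12)
  }
  # symmetry in (pred, truth)
  got_sym <- compute_metrics(truth, pred)
  expect_equal(got$mse, got_sym$mse)
  expect_equal(got$pearson, got_sym$pearson)
  # zero-variance sample vector reported as NA with a warning
  flat <- truth; flat[, 2] <- 3
  expect_warning(gm <- compute_metrics(flat, truth), "zero-variance")
  expect_true(is.na(gm$pearson[2]))
})

test_that("PCA encoder matches the eigendecomposition oracle", {
  # rank-1 data: first component carries all variance
  set.seed(10)
  u <- rnorm(12); z <- rnorm(30)
  X1 <- u %*% t(z)
  dimnames(X1) <- list(paste0("f", 1:12), paste0("s", 1:30))
  pe1 <- pca_encoder(X1, n_components = 1)
  expect_gt(pe1$sdev[1]^2 / sum(pe1$sdev^2), 1 - 1e-10)

  X <- rand_matrix(15, 40, seed = 11)
  k <- 5
  pe <- pca_encoder(X, n_components = k)
  scores <- pca_transform(pe, X)
  # training components mutually orthogonal (zero off-diagonal covariance)
  cv <- cov(t(scores))
  expect_lt(max(abs(cv[upper.tri(cv)])), 1e-10)
  # reconstruction error equals the sum of trailing eigenvalues of cov
  centered <- X - rowMeans(X)
  recon <- pe$rotation %*% scores
  resid_ss <- sum((centered - recon)^2) / (ncol(X) - 1)
  ev <- eigen(cov(t(X)), symmetric = TRUE)$values
  expect_lt(abs(resid_ss - sum(ev[-(1:k)])), 1e-8)
  expect_error(pca_encoder(X, n_components = 100), class = "drt_validation_error")
})

test_that("test rows never influence trained parameters", {
  dat <- tiny_data(n = 30)
  enc <- tiny_encoders()
  sp <- split_samples(colnames(dat$IC), seed = 12)
  cfg <- train_config(patience = NULL, max_epochs = 5, batch_size = 8, seed = 13)
  model <- assemble_model(enc$menc, enc$eenc, nrow(dat$IC), c(8, 8, 8), seed = 14)
  fit1 <- train_response_model(model, dat$M, dat$E, dat$IC, sp, cfg)
  # permute the values of the test samples in all matrices
  perm <- rev(sp$test)
  dat2 <- dat
  dat2$M[, sp$test] <- dat$M[, perm]
  dat2$E[, sp$test] <- dat$E[, perm]
  dat2$IC[, sp$test] <- dat$IC[, perm]
  fit2 <- train_response_model(model, dat2$M, dat2$E, dat2$IC, sp, cfg)
  expect_identical(fit1$model$head, fit2$model$head)
  expect_identical(fit1$model$menc, fit2$model$menc)
  # overlapping splits are rejected
  sp_bad <- sp; sp_bad$validation[1] <- sp$test[1]
  expect_error(train_response_model(model, dat$M, dat$E, dat$IC, sp_bad, cfg),
               class = "drt_validation_error")
})

test_that("single-omics and PCA-encoder variants train end to end", {
  dat <- tiny_data()
  enc <- tiny_encoders()
  sp <- split_samples(colnames(dat$IC), seed = 15)
  cfg <- train_config(patience = 3, max_epochs = 10, batch_size = 16, seed = 16)
  for (model in list(
    assemble_model(NULL, enc$eenc, nrow(dat$IC), c(8, 8, 8), seed = 17),
    assemble_model(enc$menc, NULL, nrow(dat$IC), c(8, 8, 8), seed = 17),
    assemble_model(pca_encoder(dat$M[, sp$train], 4),
                   pca_encoder(dat$E[, sp$train], 4),
                   nrow(dat$IC), c(8, 8, 8), seed = 17))) {
    fit <- train_response_model(model, dat$M, dat$E, dat$IC, sp, cfg)
    expect_true(is.finite(fit$metrics$mse))
    expect_gte(fit$metrics$epochs, 1)
  }
  # fixed PCA encoders stay fixed during training
  pm <- pca_encoder(dat$M[, sp$train], 4)
  model <- assemble_model(pm, enc$eenc, nrow(dat$IC), c(8, 8, 8), seed = 18)
  fit <- train_response_model(model, dat$M, dat$E, dat$IC, sp, cfg)
  expect_identical(fit$model$menc, pm)
})

test_that("a one-iteration benchmark produces one row per model and valid medians", {
  dat <- tiny_data(n = 40)
  enc <- tiny_encoders()
  bench <- run_benchmark(dat$M, dat$E, dat$IC, enc$menc, enc$eenc,
                         n_iter = 1, seed = 19, n_components = 4,
                         head_widths = c(8, 8, 8),
                         cfg = train_config(patience = 3, max_epochs = 5,
                                            batch_size = 16))
  expect_identical(nrow(bench$per_iteration), 7L)
  expect_identical(sort(unique(bench$per_iteration$model)),
                   sort(c("pretrained", "random_init", "pca_encoders",
                          "eenc_only", "menc_only", "linear_regression",
                          "svm_per_drug")))
  expect_true(all(is.finite(bench$per_iteration$mse)))
  # medians reproducible from the stored per-iteration values
  for (m in bench$summary$model) {
    vals <- bench$per_iteration$mse[bench$per_iteration$model == m]
    expect_identical(bench$summary$median_mse[bench$summary$model == m],
                     median(vals))
  }
  expect_error(run_benchmark(dat$M, dat$E, dat$IC, enc$menc, enc$eenc,
                             n_iter = 0), class = "drt_validation_error")
})

test_that("the median over an odd iteration count is the middle order statistic", {
  dat <- tiny_data(n = 40)
  enc <- tiny_encoders()
  bench <- run_benchmark(dat$M, dat$E, dat$IC, enc$menc, enc$eenc,
                         n_iter = 3, seed = 20, n_components = 4,
                         head_widths = c(8, 8, 8),
                         cfg = train_config(patience = 3, max_epochs = 3,
                                            batch_size = 16),
                         models = "linear_regression")
  vals <- bench$per_iteration$mse
  expect_identical(bench$summary$median_mse, sort(vals)[2])
})
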