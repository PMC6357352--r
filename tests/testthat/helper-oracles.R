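# Independent brute-force oracles, deliberately written as plain loops so
# they share no code path with the package implementations they check.

# k-nearest-drug imputation: pairwise-complete RMS distance,
# inverse-distance (or uniform) weights over the k nearest drugs observed
# at the sample.
brute_knn_impute <- function(IC, k = 5, weights = "inverse_distance",
                             epsilon = 1e-9) {
  D <- nrow(IC)
  out <- IC
  for (d in seq_len(D)) for (s in seq_len(ncol(IC))) {
    if (!is.na(IC[d, s])) next
    dists <- rep(NA_real_, D)
    for (j in seq_len(D)) {
      if (j == d) next
      shared <- !is.na(IC[d, ]) & !is.na(IC[j, ])
      if (sum(shared) > 0)
        dists[j] <- sqrt(sum((IC[d, shared] - IC[j, shared])^2) / sum(shared))
    }
    cand <- which(!is.na(IC[, s]) & !is.na(dists))
    nb <- cand[order(dists[cand], cand)][seq_len(min(k, length(cand)))]
    w <- if (weights == "uniform") rep(1, length(nb)) else 1 / (dists[nb] + epsilon)
    out[d, s] <- sum(w * IC[nb, s]) / sum(w)
  }
  out
}

# straight-line neuron-by-neuron forward pass: y_j = F(sum_i w_ij x_i + b_j)
brute_forward <- function(params, x_row) {
  a <- x_row
  for (l in seq_along(params)) {
    z <- numeric(nrow(params[[l]]$W))
    for (j in seq_along(z)) {
      acc <- params[[l]]$b[j]
      for (k in seq_along(a)) acc <- acc + params[[l]]$W[j, k] * a[k]
      z[j] <- acc
    }
    a <- if (params[[l]]$activation == "relu") pmax(z, 0) else z
  }
  a
}
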