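#' k-nearest-drug imputation of missing log-IC50 entries
#'
#' Fills each missing entry of a drug x sample response matrix with a
#' weighted mean over the k drugs nearest to the target drug. Distance
#' between two drugs is the root mean squared difference of their log-IC50
#' values over pairwise-complete samples (a scale-corrected Euclidean
#' distance, so drug pairs sharing few samples are not penalized for having
#' fewer terms). Neighbor weights are `1 / (distance + epsilon)`
#' renormalized, or uniform.
#'
#' Observed entries are never modified. For a given missing cell only
#' neighbors observed at that sample are eligible; if fewer than `k` exist,
#' all available are used with a warning.
#'
#' @param IC drug x sample matrix of log10 IC50 values with `NA` for
#'   missing entries.
#' @param k number of nearest drugs (default 5).
#' @param weights `"inverse_distance"` (default) or `"uniform"`.
#' @param epsilon ridge added to distances before inversion (default 1e-9),
#'   guarding exact-duplicate drugs.
#' @return the completed matrix (no `NA` entries).
#' @export
knn_impute_responses <- function(IC, k = 5, weights = c("inverse_distance", "uniform"),
                                 epsilon = 1e-9) {
  weights <- match.arg(weights)
  check_response_matrix(IC)
  if (k < 1) stop_validation("k must be >= 1")
  if (epsilon <= 0) stop_validation("epsilon must be > 0")
  if (!anyNA(IC)) return(IC)
  obs <- !is.na(IC)
  if (any(rowSums(obs) == 0))
    stop_validation("drug(s) with no observed entries: ",
                    paste(rownames(IC)[rowSums(obs) == 0], collapse = ", "))
  D <- nrow(IC)
  # pairwise-complete RMS distance between drug profiles
  dist_mat <- matrix(NA_real_, D, D)
  for (i in seq_len(D - 1)) {
    for (j in seq.int(i + 1, D)) {
      shared <- obs[i, ] & obs[j, ]
      if (any(shared)) {
        dist_mat[i, j] <- dist_mat[j, i] <-
          sqrt(mean((IC[i, shared] - IC[j, shared])^2))
      }
    }
  }
  out <- IC
  short <- 0L
  for (idx in which(!obs, arr.ind = FALSE)) {
    d <- (idx - 1L) %% D + 1L
    s <- (idx - 1L) %/% D + 1L
    cand <- which(obs[, s])
    cand <- cand[!is.na(dist_mat[d, cand])]
    if (!length(cand))
      stop_validation("no observed neighbor drug for cell (",
                      rownames(IC)[d], ", ", colnames(IC)[s], ")")
    if (length(cand) < k) short <- short + 1L
    ord <- cand[order(dist_mat[d, cand], cand)]
    nb <- head(ord, k)
    w <- if (weights == "uniform") rep(1, length(nb))
         else 1 / (dist_mat[d, nb] + epsilon)
    out[d, s] <- sum(w * IC[nb, s]) / sum(w)
  }
  if (short > 0)
    warning(short, " missing cell(s) had fewer than k = ", k,
            " eligible neighbor drugs; used all available")
  out
}
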