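# Synthetic cohorts with the statistical structure the pipeline assumes:
# a low-rank latent factor space shared between expression and response,
# sparse binary mutations with a few response-driving genes, and a large
# corpus plus a smaller cohort drawn from the same loadings so transfer
# from corpus to cohort is meaningful.

#' Configuration of the synthetic cohort generator
#'
#' Defaults are sized for desk-scale runs: small enough for minute-scale
#' training, large enough that the transfer benefit and planted
#' associations are detectable.
#'
#' @param latent_dim dimension k of the shared latent factors (default 8).
#' @param n_expr_genes,n_mut_genes,n_drugs matrix dimensions
#'   (defaults 300 / 200 / 30).
#' @param n_corpus,n_cohort corpus and cohort sample counts
#'   (defaults 2000 / 300).
#' @param n_drivers number of response-driving mutation genes (default 3).
#' @param driver_effect additive log-IC50 shift per driver mutation, in
#'   log10 IC50 units (default 1.0).
#' @param p_background,p_driver Bernoulli mutation probabilities for
#'   passenger and driver genes (defaults 0.05 / 0.30).
#' @param loading_scale standard deviation of expression loadings
#'   (default 0.5).
#' @param response_loading_scale standard deviation of the latent-to-
#'   response loadings u (default 0.4); set 0 for responses untied to the
#'   latent space.
#' @param noise_sd_expr,noise_sd_response Gaussian noise standard
#'   deviations (defaults 1.0 / 0.5).
#' @param missing_fraction fraction of cohort response entries masked
#'   missing at random (default 0.10).
#' @param n_strata number of strata (cancer-type stand-ins; default 3).
#' @param stratum_shift_sd sd of per-stratum latent mean shifts
#'   (default 0.5); strata differ in latent location, not in
#'   mutation-response coupling.
#' @param seed integer seed; generation is fully deterministic given it.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(latent_dim = 8, n_expr_genes = 300,
                             n_mut_genes = 200, n_drugs = 30,
                             n_corpus = 2000, n_cohort = 300,
                             n_drivers = 3, driver_effect = 1.0,
                             p_background = 0.05, p_driver = 0.30,
                             loading_scale = 0.5,
                             response_loading_scale = 0.4,
                             noise_sd_expr = 1.0, noise_sd_response = 0.5,
                             missing_fraction = 0.10, n_strata = 3,
                             stratum_shift_sd = 0.5, seed = 1L) {
  cfg <- list(latent_dim = latent_dim, n_expr_genes = n_expr_genes,
              n_mut_genes = n_mut_genes, n_drugs = n_drugs,
              n_corpus = n_corpus, n_cohort = n_cohort,
              n_drivers = n_drivers, driver_effect = driver_effect,
              p_background = p_background, p_driver = p_driver,
              loading_scale = loading_scale,
              response_loading_scale = response_loading_scale,
              noise_sd_expr = noise_sd_expr,
              noise_sd_response = noise_sd_response,
              missing_fraction = missing_fraction, n_strata = n_strata,
              stratum_shift_sd = stratum_shift_sd, seed = as.integer(seed))
  counts <- c("latent_dim", "n_expr_genes", "n_mut_genes", "n_drugs",
              "n_corpus", "n_cohort", "n_strata")
  if (any(unlist(cfg[counts]) < 1)) stop_validation("all counts must be positive")
  if (cfg$n_drivers > cfg$n_mut_genes)
    stop_validation("more drivers than mutation genes")
  for (p in c("p_background", "p_driver"))
    if (cfg[[p]] <= 0 || cfg[[p]] >= 1) stop_validation(p, " must be in (0, 1)")
  if (cfg$missing_fraction < 0 || cfg$missing_fraction >= 1)
    stop_validation("missing_fraction must be in [0, 1)")
  structure(cfg, class = "synthetic_config")
}

# Draw one set of samples (latent factors, expression, mutations) from
# fixed loadings/effects. Expression is rectified at zero with a per-gene
# mean offset of two signal+noise standard deviations, keeping >= 95% of
# entries positive before rectification (log2(TPM+1)-like support).
draw_samples <- function(cfg, truth, n, prefix, strata_of) {
  k <- cfg$latent_dim
  shift <- truth$stratum_shift[, strata_of, drop = FALSE]
  Z <- matrix(stats::rnorm(k * n), k, n) + shift
  gene_sd <- sqrt(rowSums(truth$A^2) + cfg$noise_sd_expr^2)
  mu <- 2 * gene_sd
  Eraw <- truth$A %*% Z + mu +
    matrix(stats::rnorm(cfg$n_expr_genes * n, sd = cfg$noise_sd_expr),
           cfg$n_expr_genes, n)
  E <- pmax(Eraw, 0)
  p_gene <- rep(cfg$p_background, cfg$n_mut_genes)
  p_gene[truth$driver_idx] <- cfg$p_driver
  M <- matrix(stats::rbinom(cfg$n_mut_genes * n, 1L, rep(p_gene, times = n)),
              cfg$n_mut_genes, n)
  ids <- sprintf("%s%04d", prefix, seq_len(n))
  dimnames(E) <- list(truth$expr_genes, ids)
  dimnames(M) <- list(truth$mut_genes, ids)
  list(Z = Z, E = E, M = M, ids = ids)
}

# Response from latent factors + driver effects + noise:
# ic_{d,i} = beta_d + u_d . z_i + sum_j gamma_{d,j} m_{j,i} + eps.
draw_response <- function(cfg, truth, Z, M) {
  n <- ncol(Z)
  IC <- matrix(truth$beta, cfg$n_drugs, n) + truth$U %*% Z +
    truth$Gamma %*% M +
    matrix(stats::rnorm(cfg$n_drugs * n, sd = cfg$noise_sd_response),
           cfg$n_drugs, n)
  dimnames(IC) <- list(truth$drug_ids, colnames(M))
  IC
}

generate_internal <- function(cfg, null_effects = FALSE) {
  set.seed(derive_seed(cfg$seed, 0L))
  k <- cfg$latent_dim
  truth <- list(
    expr_genes = sprintf("EG%04d", seq_len(cfg$n_expr_genes)),
    mut_genes = sprintf("MG%04d", seq_len(cfg$n_mut_genes)),
    drug_ids = sprintf("drug_%03d", seq_len(cfg$n_drugs)),
    A = matrix(stats::rnorm(cfg$n_expr_genes * k, sd = cfg$loading_scale),
               cfg$n_expr_genes, k),
    U = matrix(stats::rnorm(cfg$n_drugs * k, sd = cfg$response_loading_scale),
               cfg$n_drugs, k),
    beta = stats::rnorm(cfg$n_drugs, sd = 1),
    driver_idx = sort(sample.int(cfg$n_mut_genes, cfg$n_drivers)),
    stratum_shift = matrix(stats::rnorm(k * cfg$n_strata,
                                        sd = cfg$stratum_shift_sd),
                           k, cfg$n_strata)
  )
  # each driver gene shifts log-IC50 of one drug (cycled over the panel)
  truth$Gamma <- matrix(0, cfg$n_drugs, cfg$n_mut_genes,
                        dimnames = list(truth$drug_ids, truth$mut_genes))
  truth$driver_drugs <- ((seq_len(cfg$n_drivers) - 1L) %% cfg$n_drugs) + 1L
  truth$Gamma[cbind(truth$driver_drugs, truth$driver_idx)] <- cfg$driver_effect
  if (null_effects) {
    truth$Gamma[] <- 0
    truth$U[] <- 0
  }
  truth$driver_genes <- truth$mut_genes[truth$driver_idx]
  truth$effects <- data.frame(
    gene = truth$driver_genes,
    drug = truth$drug_ids[truth$driver_drugs],
    effect = if (null_effects) 0 else cfg$driver_effect)

  strata_labels <- sprintf("stratum_%d", seq_len(cfg$n_strata))
  set.seed(derive_seed(cfg$seed, 1L))
  corpus_strata <- sample.int(cfg$n_strata, cfg$n_corpus, replace = TRUE)
  corpus <- draw_samples(cfg, truth, cfg$n_corpus, "T", corpus_strata)
  set.seed(derive_seed(cfg$seed, 2L))
  cohort_strata <- sample.int(cfg$n_strata, cfg$n_cohort, replace = TRUE)
  cohort <- draw_samples(cfg, truth, cfg$n_cohort, "C", cohort_strata)
  IC <- draw_response(cfg, truth, cohort$Z, cohort$M)
  if (cfg$missing_fraction > 0) {
    set.seed(derive_seed(cfg$seed, 3L))
    mask <- matrix(stats::runif(length(IC)) < cfg$missing_fraction,
                   nrow(IC), ncol(IC))
    IC[mask] <- NA_real_
  }
  truth$latent_corpus <- corpus$Z
  truth$latent_cohort <- cohort$Z
  list(
    corpus = list(expression = corpus$E, mutation = corpus$M,
                  annotation = data.frame(sample_id = corpus$ids,
                                          stratum = strata_labels[corpus_strata])),
    cohort = list(expression = cohort$E, mutation = cohort$M, response = IC,
                  annotation = data.frame(sample_id = cohort$ids,
                                          stratum = strata_labels[cohort_strata])),
    truth = truth, config = cfg
  )
}

#' Generate a synthetic corpus + cohort pair
#'
#' Per sample i, latent factors `z_i` are standard normal (plus a small
#' per-stratum mean shift); expression is a rectified linear readout
#' `max(0, A z_i + mu + eps)` with the offset `mu` keeping at least 95% of
#' entries positive; mutations are Bernoulli, with driver genes mutated at
#' an elevated rate; log-IC50 response is
#' `beta_d + u_d . z_i + sum_j gamma_dj m_ji + eps`, with a configured
#' fraction of cohort entries masked missing at random. Corpus and cohort
#' are drawn from the SAME loadings and effects, so representations
#' learned on the corpus transfer to the cohort. Deterministic given the
#' config seed.
#'
#' @param cfg a [synthetic_config()].
#' @return list with `corpus` (expression, mutation, annotation), `cohort`
#'   (expression, mutation, response, annotation), `truth` (latent factors,
#'   loadings, driver effect map, per-drug baselines) and `config`.
#' @export
generate_cohort <- function(cfg = synthetic_config()) {
  stopifnot(inherits(cfg, "synthetic_config"))
  generate_internal(cfg, null_effects = FALSE)
}

#' Generate a matched null cohort
#'
#' Identical generative process with all driver effects and latent-to-
#' response loadings set to zero: responses are independent of mutations
#' and expression. Used for type-I-error calibration of the association
#' scan.
#'
#' @param cfg a [synthetic_config()].
#' @return same structure as [generate_cohort()].
#' @export
generate_null_cohort <- function(cfg = synthetic_config()) {
  stopifnot(inherits(cfg, "synthetic_config"))
  generate_internal(cfg, null_effects = TRUE)
}
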