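# Downstream pharmacogenomic statistics on (predicted) drug response:
# per-stratum and pan-cohort mutation-drug scans with Bonferroni control,
# and drug-centric extreme-responder characterization.

#' Filters for the mutation-drug association scan
#'
#' @param min_mutation_rate genes are tested only where their mutation rate
#'   in the stratum is strictly greater than this fraction (default 0.10).
#' @param min_carriers minimum carrier count, applied in the stratified
#'   scan only (default 10).
#' @param alpha_adjusted significance threshold on the Bonferroni-adjusted
#'   P value (default 1e-5).
#' @return list of class `scan_filter`.
#' @export
scan_filter <- function(min_mutation_rate = 0.10, min_carriers = 10,
                        alpha_adjusted = 1e-5) {
  if (min_mutation_rate <= 0 || min_mutation_rate >= 1)
    stop_validation("min_mutation_rate must be in (0, 1)")
  if (min_carriers < 0) stop_validation("min_carriers must be >= 0")
  if (alpha_adjusted <= 0) stop_validation("alpha_adjusted must be > 0")
  structure(list(min_mutation_rate = min_mutation_rate,
                 min_carriers = as.integer(min_carriers),
                 alpha_adjusted = alpha_adjusted),
            class = "scan_filter")
}

# Vectorized Welch (or pooled) two-sample t-test of each row of Y between
# carrier and wildtype sample sets. Returns delta (carrier - wildtype
# mean), t, df, p.
row_t_tests <- function(Y, carriers, wildtype, pooled = FALSE) {
  Y1 <- Y[, carriers, drop = FALSE]
  Y0 <- Y[, wildtype, drop = FALSE]
  n1 <- length(carriers); n0 <- length(wildtype)
  m1 <- rowMeans(Y1); m0 <- rowMeans(Y0)
  v1 <- rowSums((Y1 - m1)^2) / (n1 - 1)
  v0 <- rowSums((Y0 - m0)^2) / (n0 - 1)
  delta <- m1 - m0
  if (pooled) {
    sp2 <- ((n1 - 1) * v1 + (n0 - 1) * v0) / (n1 + n0 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n0))
    df <- rep(n1 + n0 - 2, length(delta))
  } else {
    se <- sqrt(v1 / n1 + v0 / n0)
    df <- (v1 / n1 + v0 / n0)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v0 / n0)^2 / (n0 - 1))
  }
  t_stat <- delta / se
  p <- 2 * stats::pt(-abs(t_stat), df)
  # identical groups: zero difference and zero variance -> no evidence
  degenerate <- !is.finite(t_stat)
  t_stat[degenerate & delta == 0] <- 0
  p[degenerate & delta == 0] <- 1
  list(delta = delta, t = t_stat, df = df, p = p)
}

#' Scan mutation-drug associations in predicted response
#'
#' For each admissible (stratum, gene) pair — mutation rate strictly above
#' `min_mutation_rate` and, in stratified mode, carrier count at least
#' `min_carriers` — and each drug, a two-tailed Welch t-test compares
#' predicted log-IC50 between mutation carriers and wildtype samples.
#' Bonferroni adjustment multiplies each raw P by the total number of tests
#' emitted by the scan (capped at 1); a record is flagged significant when
#' the adjusted P falls below `alpha_adjusted`. A positive delta
#' (carrier mean minus wildtype mean) marks a resistance-associated
#' mutation, a negative delta a sensitizing one.
#'
#' @param predIC drug x sample matrix of (predicted) log-IC50.
#' @param M gene x sample binary mutation matrix, samples aligned with
#'   `predIC`.
#' @param strata named character vector (sample -> stratum label), a
#'   sample annotation data.frame, or `NULL` for a pan-cohort scan.
#' @param filt a [scan_filter()].
#' @param pooled use the pooled-variance t-test instead of Welch.
#' @return data.frame of class `association_records`, one row per
#'   (stratum, gene, drug) test: `stratum`, `gene`, `drug`, `delta_ic50`,
#'   `t`, `df`, `p`, `p_adj`, `n_mut`, `n_wt`, `direction`, `significant`.
#' @export
mutation_drug_scan <- function(predIC, M, strata = NULL, filt = scan_filter(),
                               pooled = FALSE) {
  check_feature_matrix(predIC, "predIC")
  check_mutation_matrix(M)
  samples <- colnames(predIC)
  if (!identical(colnames(M), samples))
    stop_validation("predIC and M must share ordered sample ids")
  if (is.data.frame(strata)) strata <- strata_for_samples(strata, samples)
  stratified <- !is.null(strata)
  if (stratified) {
    if (is.null(names(strata)) || !all(samples %in% names(strata)))
      stop_validation("strata labels must cover all samples")
    strata <- strata[samples]
    groups <- split(seq_along(samples), strata)
  } else {
    groups <- list(pan = seq_along(samples))
  }
  out <- list()
  skipped <- 0L
  for (stratum in names(groups)) {
    idx <- groups[[stratum]]
    n_str <- length(idx)
    Mg <- M[, idx, drop = FALSE]
    rate <- rowMeans(Mg)
    carriers_n <- rowSums(Mg)
    admissible <- rate > filt$min_mutation_rate
    if (stratified) admissible <- admissible & carriers_n >= filt$min_carriers
    for (g in which(admissible)) {
      car <- idx[Mg[g, ] == 1]
      wt <- idx[Mg[g, ] == 0]
      if (length(car) < 2 || length(wt) < 2) { skipped <- skipped + 1L; next }
      tt <- row_t_tests(predIC, car, wt, pooled = pooled)
      out[[length(out) + 1L]] <- data.frame(
        stratum = stratum, gene = rownames(M)[g], drug = rownames(predIC),
        delta_ic50 = tt$delta, t = tt$t, df = tt$df, p = tt$p,
        n_mut = length(car), n_wt = length(wt),
        row.names = NULL)
    }
  }
  if (skipped > 0)
    warning(skipped, " gene-stratum pair(s) passed filters but had a group ",
            "with < 2 samples; skipped")
  if (!length(out)) {
    rec <- data.frame(stratum = character(0), gene = character(0),
                      drug = character(0), delta_ic50 = numeric(0),
                      t = numeric(0), df = numeric(0), p = numeric(0),
                      p_adj = numeric(0), n_mut = integer(0), n_wt = integer(0),
                      direction = character(0), significant = logical(0))
    return(structure(rec, class = c("association_records", "data.frame"),
                     n_tests = 0L))
  }
  rec <- do.call(rbind, out)
  m <- nrow(rec)
  rec$p_adj <- pmin(1, rec$p * m)
  rec$direction <- ifelse(rec$delta_ic50 > 0, "resistant",
                          ifelse(rec$delta_ic50 < 0, "sensitive", "none"))
  rec$significant <- rec$p_adj < filt$alpha_adjusted
  structure(rec, class = c("association_records", "data.frame"), n_tests = m)
}

#' Summarize a scan's significant records by direction
#'
#' @param records output of [mutation_drug_scan()].
#' @return list with counts of significant records, resistant and sensitive
#'   counts, and their percentage shares (one decimal, as conventionally
#'   reported).
#' @export
summarize_scan <- function(records) {
  sig <- records[records$significant, , drop = FALSE]
  n_res <- sum(sig$direction == "resistant")
  n_sen <- sum(sig$direction == "sensitive")
  n_sig <- nrow(sig)
  list(n_tests = attr(records, "n_tests"),
       n_significant = n_sig,
       n_resistant = n_res, n_sensitive = n_sen,
       pct_resistant = if (n_sig) round(100 * n_res / n_sig, 1) else NA_real_,
       pct_sensitive = if (n_sig) round(100 * n_sen / n_sig, 1) else NA_real_)
}

#' Extreme-responder groups for one drug
#'
#' Samples whose predicted log-IC50 lies in the bottom `fraction` form the
#' sensitive group, the top `fraction` the resistant group; group size is
#' `ceiling(fraction * n)` and ties are broken by stable sample-id order.
#'
#' @param pred_row named numeric vector: predicted log-IC50 per sample for
#'   one drug.
#' @param fraction tail fraction per group (default 0.01).
#' @return list with character vectors `sensitive` and `resistant`, and
#'   `size`.
#' @export
extreme_responder_groups <- function(pred_row, fraction = 0.01) {
  if (fraction <= 0 || fraction >= 0.5)
    stop_validation("fraction must be in (0, 0.5)")
  n <- length(pred_row)
  if (is.null(names(pred_row))) stop_validation("pred_row must carry sample names")
  size <- as.integer(ceiling(fraction * n))
  if (2L * size > n)
    stop_validation("groups of size ", size, " would overlap at n = ", n)
  ord <- order(pred_row, names(pred_row))
  list(sensitive = names(pred_row)[ord[seq_len(size)]],
       resistant = names(pred_row)[ord[seq.int(n - size + 1L, n)]],
       size = size)
}

#' Characterize extreme-responder groups
#'
#' Reports (i) the stratum (e.g., cancer type) composition of each group in
#' percent, (ii) the per-gene mutation-rate difference (sensitive minus
#' resistant) ranked by absolute difference, and (iii) a differential
#' expression table (two-tailed Welch t-test per gene between groups)
#' ranked by raw P with ties broken by absolute effect size.
#'
#' @param groups list with `sensitive` and `resistant` sample-id vectors
#'   (from [extreme_responder_groups()]).
#' @param M gene x sample mutation matrix (or `NULL` to skip).
#' @param E gene x sample expression matrix (or `NULL` to skip).
#' @param strata named sample -> stratum vector or annotation data.frame.
#' @param top_n_expr length of the reported top differential-expression
#'   gene list (default 300).
#' @param top_n_mut number of top differentially mutated genes (default 10).
#' @return list of class `responder_report`: `composition` (data.frame of
#'   percent per stratum and group), `mutation_rates` (all genes, ranked),
#'   `top_mutated`, `expression` (all genes, ranked), `top_expressed`
#'   (character vector of gene ids), and the group sizes.
#' @export
group_characterization <- function(groups, M = NULL, E = NULL, strata = NULL,
                                   top_n_expr = 300, top_n_mut = 10) {
  sens <- groups$sensitive; res <- groups$resistant
  if (!length(sens) || !length(res)) stop_validation("empty responder group")
  if (length(intersect(sens, res))) stop_validation("groups must be disjoint")
  report <- list(n_sensitive = length(sens), n_resistant = length(res))

  if (!is.null(strata)) {
    if (is.data.frame(strata))
      strata <- strata_for_samples(strata, union(sens, res))
    comp <- function(ids) {
      tab <- table(strata[ids])
      100 * as.numeric(tab) / length(ids) -> pct
      data.frame(stratum = names(tab), percent = pct, row.names = NULL)
    }
    cs <- comp(sens); cr <- comp(res)
    all_strata <- sort(union(cs$stratum, cr$stratum))
    report$composition <- data.frame(
      stratum = all_strata,
      sensitive_pct = cs$percent[match(all_strata, cs$stratum)],
      resistant_pct = cr$percent[match(all_strata, cr$stratum)])
    report$composition[is.na(report$composition)] <- 0
  }

  if (!is.null(M)) {
    rate_s <- rowMeans(M[, sens, drop = FALSE])
    rate_r <- rowMeans(M[, res, drop = FALSE])
    tab <- data.frame(gene = rownames(M), rate_sensitive = rate_s,
                      rate_resistant = rate_r, rate_diff = rate_s - rate_r,
                      row.names = NULL)
    tab <- tab[order(-abs(tab$rate_diff), tab$gene), , drop = FALSE]
    rownames(tab) <- NULL
    report$mutation_rates <- tab
    report$top_mutated <- head(tab, min(top_n_mut, nrow(tab)))
  }

  if (!is.null(E)) {
    if (length(sens) < 2 || length(res) < 2)
      stop_validation("need >= 2 samples per group for differential expression")
    tt <- row_t_tests(E, match(sens, colnames(E)), match(res, colnames(E)))
    de <- data.frame(gene = rownames(E), delta = tt$delta, t = tt$t,
                     p = tt$p,
                     direction = ifelse(tt$delta > 0, "up_in_sensitive",
                                        "up_in_resistant"),
                     row.names = NULL)
    de <- de[order(de$p, -abs(de$delta), de$gene), , drop = FALSE]
    rownames(de) <- NULL
    report$expression <- de
    report$top_expressed <- head(de$gene, min(top_n_expr, nrow(de)))
  }
  structure(report, class = "responder_report")
}

#' Mean mutation burden of a sample group over a gene subset
#'
#' The average, over group samples, of the number of mutated genes within
#' the subset (e.g., the top differentially mutated genes).
#'
#' @param group character vector of sample ids.
#' @param M gene x sample binary mutation matrix.
#' @param gene_subset character vector of gene ids.
#' @return a single number.
#' @export
mean_mutation_burden <- function(group, M, gene_subset) {
  if (!length(group)) stop_validation("empty group")
  if (!length(gene_subset)) stop_validation("empty gene subset")
  missing_genes <- setdiff(gene_subset, rownames(M))
  if (length(missing_genes))
    stop_validation("genes not in matrix: ", paste(head(missing_genes, 5), collapse = ", "))
  mean(colSums(M[gene_subset, group, drop = FALSE]))
}
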