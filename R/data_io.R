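#' Read a feature x sample matrix from TSV/CSV
#'
#' Expects the first column to hold feature ids (genes or drugs) and the
#' header row to hold sample ids. Compressed (`.gz`) files are read
#' transparently. Empty cells and `NA` are treated as missing.
#'
#' @param path file path (TSV or CSV, optionally gzipped).
#' @param transpose if `TRUE` the file is sample-major (samples in rows) and
#'   is transposed to the package's feature-major convention on read.
#' @return a numeric matrix, features in rows, samples in columns.
#' @export
read_matrix_tsv <- function(path, transpose = FALSE) {
  if (!file.exists(path)) stop_validation("input file not found: ", path)
  if (grepl("\\.gz$", path)) {
    con <- gzfile(path, "r")
    on.exit(close(con))
    txt <- readLines(con)
    dt <- data.table::fread(text = txt, header = TRUE, data.table = FALSE,
                            na.strings = c("NA", ""))
  } else {
    dt <- data.table::fread(path, header = TRUE, data.table = FALSE,
                            na.strings = c("NA", ""))
  }
  if (ncol(dt) < 2) stop_validation(path, ": needs an id column plus data columns")
  ids <- as.character(dt[[1]])
  m <- as.matrix(dt[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  if (transpose) m <- t(m)
  check_feature_matrix(m, basename(path), allow_na = TRUE)
  m
}

#' Write a feature x sample matrix to TSV
#'
#' Values are written with 17 significant digits so that a read/write
#' round-trip reproduces the matrix to full double precision. Missing
#' entries are written as `NA`. A `.gz` suffix triggers gzip compression.
#'
#' @param x numeric matrix with dimnames.
#' @param path output path.
#' @param id_column header name of the first (feature id) column.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(x, path, id_column = "feature_id") {
  check_feature_matrix(x, "matrix", allow_na = TRUE)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(paste(c(id_column, colnames(x)), collapse = "\t"), con)
  body <- vapply(seq_len(nrow(x)), function(i) {
    vals <- sprintf("%.17g", x[i, ])
    vals[is.na(x[i, ])] <- "NA"
    paste(c(rownames(x)[i], vals), collapse = "\t")
  }, character(1))
  writeLines(body, con)
  invisible(path)
}

#' Transform a TPM matrix to log2(TPM + 1)
#'
#' Expression values are modeled throughout on the log2(TPM + 1) scale.
#'
#' @param tpm gene x sample matrix of nonnegative, finite TPM values.
#' @return gene x sample matrix of log2(TPM + 1) values.
#' @export
log2_tpm_transform <- function(tpm) {
  check_feature_matrix(tpm, "TPM matrix")
  if (any(tpm < 0)) {
    bad <- which(tpm < 0, arr.ind = TRUE)[1, , drop = TRUE]
    stop_validation("TPM matrix: negative value at gene '", rownames(tpm)[bad[1]],
                    "', sample '", colnames(tpm)[bad[2]], "'")
  }
  log2(tpm + 1)
}

#' Remove genes with low information burden
#'
#' Drops genes whose expression carries little signal across the corpus:
#' a gene is retained only if its row mean is at least `mean_thr` AND its
#' row standard deviation is at least `sd_thr`. Applied on the
#' log2(TPM + 1) scale. Gene order is preserved.
#'
#' @param E gene x sample expression matrix, log2(TPM + 1) scale.
#' @param mean_thr minimum row mean (default 1).
#' @param sd_thr minimum row standard deviation (default 0.5).
#' @return the filtered expression matrix.
#' @export
filter_low_information_genes <- function(E, mean_thr = 1, sd_thr = 0.5) {
  check_expression_matrix(E)
  if (ncol(E) < 2)
    stop_validation("need at least 2 samples to compute per-gene st. dev.")
  mu <- rowMeans(E)
  s <- apply(E, 1L, stats::sd)
  keep <- (mu >= mean_thr) & (s >= sd_thr)
  E[keep, , drop = FALSE]
}

#' Variant classes counted as nonsynonymous
#'
#' The default mapping from MAF `Variant_Classification` strings to the four
#' qualifying nonsynonymous classes: missense, nonsense, frameshift
#' insertion, frameshift deletion. User-extensible via the
#' `qualifying` argument of [maf_to_mutation_matrix()].
#'
#' @return character vector of qualifying MAF classification strings.
#' @export
nonsynonymous_classes <- function() {
  c("Missense_Mutation", "Nonsense_Mutation", "Frame_Shift_Ins", "Frame_Shift_Del")
}

#' Read a MAF-like mutation table
#'
#' Requires columns for the sample barcode, the Hugo gene symbol and the
#' variant classification; column names are configurable for non-standard
#' dialects.
#'
#' @param path MAF-like TSV path (optionally gzipped).
#' @param sample_col,gene_col,class_col column names holding sample barcode,
#'   gene symbol and variant classification.
#' @return a data.frame with columns `sample`, `gene`, `classification`.
#' @export
read_maf <- function(path, sample_col = "Tumor_Sample_Barcode",
                     gene_col = "Hugo_Symbol",
                     class_col = "Variant_Classification") {
  if (!file.exists(path)) stop_validation("MAF file not found: ", path)
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE, sep = "\t")
  missing_cols <- setdiff(c(sample_col, gene_col, class_col), names(dt))
  if (length(missing_cols))
    stop_validation("MAF is missing required columns: ",
                    paste(missing_cols, collapse = ", "))
  data.frame(sample = as.character(dt[[sample_col]]),
             gene = as.character(dt[[gene_col]]),
             classification = as.character(dt[[class_col]]),
             stringsAsFactors = FALSE)
}

#' Build a binary mutation matrix from MAF-style records
#'
#' Entry (gene, sample) is 1 iff at least one record for that pair carries a
#' qualifying nonsynonymous classification; duplicate records are idempotent
#' and record order is irrelevant.
#'
#' @param records data.frame with columns `sample`, `gene`,
#'   `classification` (as returned by [read_maf()]).
#' @param gene_ids,sample_ids the gene and sample universes of the output.
#' @param qualifying classification strings that set an entry to 1.
#' @param unknown_samples what to do with records whose sample is not in
#'   `sample_ids`: `"warn"` skips them with a warning, `"error"` aborts,
#'   `"skip"` drops them silently.
#' @return a binary gene x sample matrix.
#' @export
maf_to_mutation_matrix <- function(records, gene_ids, sample_ids,
                                   qualifying = nonsynonymous_classes(),
                                   unknown_samples = c("warn", "error", "skip")) {
  unknown_samples <- match.arg(unknown_samples)
  stopifnot(all(c("sample", "gene", "classification") %in% names(records)))
  if (anyDuplicated(gene_ids)) stop_validation("gene_ids must be unique")
  if (anyDuplicated(sample_ids)) stop_validation("sample_ids must be unique")
  unknown <- setdiff(unique(records$sample), sample_ids)
  if (length(unknown)) {
    if (unknown_samples == "error")
      stop_validation("MAF records reference unknown samples: ",
                      paste(head(unknown, 5), collapse = ", "))
    if (unknown_samples == "warn")
      warning(length(unknown), " MAF sample(s) not in sample_ids; skipped: ",
              paste(head(unknown, 5), collapse = ", "))
    records <- records[records$sample %in% sample_ids, , drop = FALSE]
  }
  records <- records[records$classification %in% qualifying &
                       records$gene %in% gene_ids, , drop = FALSE]
  M <- matrix(0, length(gene_ids), length(sample_ids),
              dimnames = list(gene_ids, sample_ids))
  if (nrow(records))
    M[cbind(match(records$gene, gene_ids), match(records$sample, sample_ids))] <- 1
  M
}

#' Drop genes never mutated in either cohort
#'
#' Removes genes whose row sum is zero in both matrices; both outputs keep
#' the same (order-preserved) gene set.
#'
#' @param M_a,M_b binary mutation matrices sharing a gene universe.
#' @return a list with elements `a` and `b`, the filtered matrices.
#' @export
drop_never_mutated_genes <- function(M_a, M_b) {
  check_mutation_matrix(M_a, "M_a"); check_mutation_matrix(M_b, "M_b")
  if (!setequal(rownames(M_a), rownames(M_b)))
    stop_validation("mutation matrices must share a gene universe")
  M_b <- M_b[rownames(M_a), , drop = FALSE]
  keep <- rowSums(M_a) + rowSums(M_b) > 0
  list(a = M_a[keep, , drop = FALSE], b = M_b[keep, , drop = FALSE])
}

#' Restrict two feature matrices to their common gene universe
#'
#' Both outputs are row-aligned to the sorted intersection of their feature
#' ids, so downstream code can assume identical gene order.
#'
#' @param A,B matrices with feature ids as rownames.
#' @return list with elements `a` and `b`, rows identically ordered.
#' @export
intersect_gene_universe <- function(A, B) {
  common <- sort(intersect(rownames(A), rownames(B)))
  if (!length(common)) stop_validation("gene universes are disjoint")
  list(a = A[common, , drop = FALSE], b = B[common, , drop = FALSE])
}

#' Read a sample annotation table
#'
#' Two required columns: `sample_id` and `stratum` (e.g., cancer type);
#' extra columns (clinical flags such as receptor status) are carried along.
#'
#' @param path TSV path.
#' @return data.frame with one row per sample.
#' @export
read_sample_annotation <- function(path) {
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE, sep = "\t")
  if (!all(c("sample_id", "stratum") %in% names(dt)))
    stop_validation("annotation needs columns sample_id and stratum")
  if (anyDuplicated(dt$sample_id))
    stop_validation("annotation has duplicated sample_id entries")
  dt$sample_id <- as.character(dt$sample_id)
  dt$stratum <- as.character(dt$stratum)
  dt
}

#' Write a sample annotation table
#'
#' @param ann data.frame with `sample_id` and `stratum` columns.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_sample_annotation <- function(ann, path) {
  stopifnot(all(c("sample_id", "stratum") %in% names(ann)))
  data.table::fwrite(ann, path, sep = "\t")
  invisible(path)
}

# Named vector of stratum labels aligned to sample ids, from an annotation
# data.frame; errors on samples without a label.
strata_for_samples <- function(ann, sample_ids) {
  idx <- match(sample_ids, ann$sample_id)
  if (anyNA(idx))
    stop_validation("annotation is missing samples: ",
                    paste(head(sample_ids[is.na(idx)], 5), collapse = ", "))
  stats::setNames(ann$stratum[idx], sample_ids)
}
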