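# Classed error conditions so the CLI can map failures to exit codes:
# validation errors -> 3, numerical failures -> 4, usage errors -> 2.

validation_error <- function(msg, call = sys.call(-1)) {
  structure(
    class = c("drt_validation_error", "error", "condition"),
    list(message = msg, call = call)
  )
}

numerical_error <- function(msg, call = sys.call(-1)) {
  structure(
    class = c("drt_numerical_error", "error", "condition"),
    list(message = msg, call = call)
  )
}

usage_error <- function(msg, call = sys.call(-1)) {
  structure(
    class = c("drt_usage_error", "error", "condition"),
    list(message = msg, call = call)
  )
}

stop_validation <- function(...) stop(validation_error(paste0(...)))
stop_numerical <- function(...) stop(numerical_error(paste0(...)))
stop_usage <- function(...) stop(usage_error(paste0(...)))

# A feature x sample matrix must carry unique dimnames and (optionally)
# finite values. Returns the matrix invisibly so checks can be chained.
check_feature_matrix <- function(x, what = "matrix", finite = TRUE,
                                 allow_na = FALSE) {
  if (!is.matrix(x) || !is.numeric(x))
    stop_validation(what, " must be a numeric matrix")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop_validation(what, " must have row (feature) and column (sample) names")
  if (anyDuplicated(rownames(x)))
    stop_validation(what, ": duplicated feature ids: ",
                    paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", "))
  if (anyDuplicated(colnames(x)))
    stop_validation(what, ": duplicated sample ids: ",
                    paste(unique(colnames(x)[duplicated(colnames(x))]), collapse = ", "))
  if (finite) {
    vals <- x
    if (allow_na) vals <- vals[!is.na(vals)]
    if (any(!is.finite(vals))) {
      bad <- which(!is.finite(x) & (!allow_na | !is.na(x)), arr.ind = TRUE)[1, , drop = TRUE]
      stop_validation(what, ": non-finite value at gene/feature '",
                      rownames(x)[bad[1]], "', sample '", colnames(x)[bad[2]], "'")
    }
  }
  invisible(x)
}

check_expression_matrix <- function(x, what = "expression matrix") {
  check_feature_matrix(x, what)
  if (any(x < 0)) {
    bad <- which(x < 0, arr.ind = TRUE)[1, , drop = TRUE]
    stop_validation(what, ": negative value at gene '", rownames(x)[bad[1]],
                    "', sample '", colnames(x)[bad[2]], "'")
  }
  invisible(x)
}

check_mutation_matrix <- function(x, what = "mutation matrix") {
  check_feature_matrix(x, what)
  if (!all(x %in% c(0, 1)))
    stop_validation(what, " must be binary (0/1)")
  invisible(x)
}

check_response_matrix <- function(x, what = "response matrix") {
  check_feature_matrix(x, what, allow_na = TRUE)
  invisible(x)
}
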