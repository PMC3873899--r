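#' Expression matrix container
#'
#' Wraps a features x samples real matrix together with a platform label and a
#' normalization state.  Feature identifiers (gene symbols or antibody names)
#' must be unique after case folding; sample identifiers must be unique.
#' Missing values are allowed and propagate through every transform.
#'
#' The normalization state moves only forward along the pipeline:
#' `raw -> logged -> median_centered`, with `robust_z` reachable from any
#' state (used for tumor cohorts scored against cell-line signatures).
#'
#' @param values numeric matrix, features in rows and samples in columns, with
#'   complete `dimnames`.
#' @param platform platform label, e.g. `"gene_array"`, `"rnaseq"`, `"rppa"`.
#' @param norm_state one of `"raw"`, `"logged"`, `"median_centered"`,
#'   `"robust_z"`.
#' @return An object of class `expression_matrix`.
#' @examples
#' m <- matrix(1:6, 2, 3, dimnames = list(c("TP53", "ERBB2"), c("s1", "s2", "s3")))
#' expression_matrix(m, platform = "gene_array")
#' @export
expression_matrix <- function(values, platform = "unspecified",
                              norm_state = c("raw", "logged",
                                             "median_centered", "robust_z")) {
  norm_state <- match.arg(norm_state)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("'values' must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(values)) && nrow(values) > 0) {
    stop("feature identifiers (rownames) are required", call. = FALSE)
  }
  if (is.null(colnames(values)) && ncol(values) > 0) {
    stop("sample identifiers (colnames) are required", call. = FALSE)
  }
  assert_unique_folded(rownames(values), "feature identifiers")
  if (anyDuplicated(colnames(values))) {
    stop("duplicate sample identifiers", call. = FALSE)
  }
  structure(
    list(values = values, platform = platform, norm_state = norm_state,
         zero_variance_features = character(0)),
    class = "expression_matrix"
  )
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d features x %d samples | platform=%s | norm_state=%s\n",
              nrow(x$values), ncol(x$values), x$platform, x$norm_state))
  if (length(x$zero_variance_features) > 0) {
    cat(sprintf("  zero-variance features: %d\n", length(x$zero_variance_features)))
  }
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Drug response table container
#'
#' Wraps a drugs x cell-lines matrix of growth-inhibition readouts (GI50/IC50
#' concentrations, or values already on the negative-log scale).  When
#' `transform_state = "neglog"` a larger value means a more sensitive line.
#'
#' @param values numeric matrix, drugs in rows and cell lines in columns, with
#'   complete `dimnames`; missing entries allowed.
#' @param transform_state `"raw_concentration"` or `"neglog"`.
#' @return An object of class `drug_response_table`.
#' @export
drug_response_table <- function(values,
                                transform_state = c("raw_concentration",
                                                    "neglog")) {
  transform_state <- match.arg(transform_state)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("'values' must be a numeric matrix", call. = FALSE)
  }
  if ((is.null(rownames(values)) && nrow(values) > 0) ||
      (is.null(colnames(values)) && ncol(values) > 0)) {
    stop("drug and cell-line identifiers are required as dimnames", call. = FALSE)
  }
  assert_unique_folded(rownames(values), "drug identifiers")
  assert_unique_folded(colnames(values), "cell-line identifiers")
  all_missing <- rownames(values)[rowSums(!is.na(values)) == 0]
  structure(
    list(values = values, transform_state = transform_state,
         all_missing_drugs = all_missing),
    class = "drug_response_table"
  )
}

#' @export
print.drug_response_table <- function(x, ...) {
  cat(sprintf("<drug_response_table> %d drugs x %d cell lines | transform_state=%s\n",
              nrow(x$values), ncol(x$values), x$transform_state))
  if (length(x$all_missing_drugs) > 0) {
    cat(sprintf("  all-missing drugs: %s\n",
                paste(x$all_missing_drugs, collapse = ", ")))
  }
  invisible(x)
}

#' @export
dim.drug_response_table <- function(x) dim(x$values)

#' Restrict containers to a subset of samples
#'
#' @param x an `expression_matrix` or `drug_response_table`.
#' @param samples character vector of sample / cell-line identifiers to keep
#'   (matched case-folded; kept in the order given).
#' @return Object of the same class restricted to `samples`.
#' @export
subset_samples <- function(x, samples) UseMethod("subset_samples")

#' @export
subset_samples.expression_matrix <- function(x, samples) {
  idx <- match(fold_id(samples), fold_id(colnames(x$values)))
  if (anyNA(idx)) {
    stop("unknown sample identifiers: ",
         paste(head(samples[is.na(idx)], 5), collapse = ", "), call. = FALSE)
  }
  out <- x
  out$values <- x$values[, idx, drop = FALSE]
  out
}

#' @export
subset_samples.drug_response_table <- function(x, samples) {
  idx <- match(fold_id(samples), fold_id(colnames(x$values)))
  if (anyNA(idx)) {
    stop("unknown cell-line identifiers: ",
         paste(head(samples[is.na(idx)], 5), collapse = ", "), call. = FALSE)
  }
  drug_response_table(x$values[, idx, drop = FALSE],
                      transform_state = x$transform_state)
}
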