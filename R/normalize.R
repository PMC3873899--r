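# per-dataset transforms applied before any correlation

#' Log-transform an expression matrix
#'
#' Applies `log_base(value + offset)` elementwise, leaving missing values
#' missing.  Expression platforms conventionally use base 2; the base only
#' rescales each feature row and Pearson correlation is affine-invariant per
#' variable, so the downstream signatures do not depend on it.
#'
#' @param expr an [expression_matrix()] with `norm_state = "raw"`.
#' @param base logarithm base (default 2).
#' @param offset added before logging (use 1 for count-like RNA-seq values).
#' @return The transformed `expression_matrix` with `norm_state = "logged"`.
#' @export
log_transform <- function(expr, base = 2, offset = 0) {
  stopifnot(inherits(expr, "expression_matrix"))
  if (expr$norm_state != "raw") {
    stop(sprintf("double transform: norm_state is already '%s'", expr$norm_state),
         call. = FALSE)
  }
  v <- expr$values + offset
  bad <- which(!is.na(v) & v <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    ex <- paste(sprintf("%s/%s", rownames(expr$values)[bad[, 1]],
                        colnames(expr$values)[bad[, 2]])[seq_len(min(5, nrow(bad)))],
                collapse = ", ")
    stop(sprintf("nonpositive value + offset for %d cell(s), e.g. %s",
                 nrow(bad), ex), call. = FALSE)
  }
  expr$values <- log(v, base = base)
  expr$norm_state <- "logged"
  expr
}

#' Median-center each feature across samples
#'
#' Subtracts from every feature row its median over non-missing samples, the
#' centering applied to every training dataset before signature construction.
#' A feature with all values missing is left missing with a warning.
#'
#' @param expr an [expression_matrix()], normally with `norm_state = "logged"`.
#' @param allow_raw permit centering of raw (unlogged) values.
#' @return The centered `expression_matrix` with `norm_state = "median_centered"`.
#' @export
median_center <- function(expr, allow_raw = FALSE) {
  stopifnot(inherits(expr, "expression_matrix"))
  if (expr$norm_state == "raw" && !allow_raw) {
    stop("input is raw; log_transform() first or set allow_raw = TRUE",
         call. = FALSE)
  }
  if (!expr$norm_state %in% c("raw", "logged")) {
    stop(sprintf("cannot median-center from norm_state '%s'", expr$norm_state),
         call. = FALSE)
  }
  med <- apply(expr$values, 1, median, na.rm = TRUE)
  empty <- !is.finite(med)
  if (any(empty)) {
    warning(sprintf("%d all-missing feature row(s) left missing: %s",
                    sum(empty),
                    paste(head(rownames(expr$values)[empty], 5), collapse = ", ")),
            call. = FALSE)
    med[empty] <- 0
  }
  expr$values <- expr$values - med
  expr$norm_state <- "median_centered"
  expr
}

#' Robust z-score: standard deviations from the median
#'
#' Normalizes each feature across samples to
#' `(value - row median) / row SD` (sample SD, n-1 denominator, over
#' non-missing entries) — the tumor-cohort normalization used before
#' projecting cell-line signatures onto tumors.  Zero-variance rows are set
#' to all zeros and flagged in `zero_variance_features` rather than erroring.
#'
#' @param expr an [expression_matrix()] in any normalization state.
#' @return The scaled `expression_matrix` with `norm_state = "robust_z"`.
#' @export
robust_zscore <- function(expr) {
  stopifnot(inherits(expr, "expression_matrix"))
  med <- apply(expr$values, 1, median, na.rm = TRUE)
  sdv <- apply(expr$values, 1, sd, na.rm = TRUE)
  med[!is.finite(med)] <- 0
  zero_var <- !is.finite(sdv) | sdv == 0
  centered <- expr$values - med
  scale <- ifelse(zero_var, 1, sdv)
  out <- centered / scale
  out[zero_var, ] <- 0
  # preserve the original missingness mask exactly
  out[is.na(expr$values)] <- NA_real_
  expr$values <- out
  expr$norm_state <- "robust_z"
  expr$zero_variance_features <- rownames(expr$values)[zero_var]
  expr
}

#' Negative-log transform of drug response concentrations
#'
#' Converts GI50/IC50 concentrations to `-log_base(concentration)` so that a
#' larger value means a more sensitive cell line.
#'
#' @param response a [drug_response_table()] with
#'   `transform_state = "raw_concentration"`; all non-missing values must be
#'   positive.
#' @param base logarithm base (default 10, the conventional molar scale).
#' @return The table with `transform_state = "neglog"`.
#' @export
neglog_response <- function(response, base = 10) {
  stopifnot(inherits(response, "drug_response_table"))
  if (response$transform_state != "raw_concentration") {
    stop("response values are already on the negative-log scale", call. = FALSE)
  }
  bad <- which(!is.na(response$values) & response$values <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("nonpositive concentration for %d cell(s), e.g. %s/%s",
                 nrow(bad), rownames(response$values)[bad[1, 1]],
                 colnames(response$values)[bad[1, 2]]), call. = FALSE)
  }
  response$values <- -log(response$values, base = base)
  response$transform_state <- "neglog"
  response
}
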