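# broom-style tidiers for every result type

#' Tidy an expression matrix into long format
#'
#' @param x an [expression_matrix()].
#' @param ... unused.
#' @return Tibble with columns `feature`, `sample`, `value`.
#' @method tidy expression_matrix
#' @export
tidy.expression_matrix <- function(x, ...) {
  tibble::as_tibble(x$values, rownames = "feature") |>
    tidyr::pivot_longer(-"feature", names_to = "sample", values_to = "value")
}

#' @method glance expression_matrix
#' @export
glance.expression_matrix <- function(x, ...) {
  tibble::tibble(
    n_features = nrow(x$values), n_samples = ncol(x$values),
    platform = x$platform, norm_state = x$norm_state,
    missing_fraction = mean(is.na(x$values)),
    n_zero_variance = length(x$zero_variance_features)
  )
}

#' Tidy a drug response table into long format
#'
#' @param x a [drug_response_table()].
#' @param ... unused.
#' @return Tibble with columns `drug`, `cell_line`, `value`.
#' @method tidy drug_response_table
#' @export
tidy.drug_response_table <- function(x, ...) {
  tibble::as_tibble(x$values, rownames = "drug") |>
    tidyr::pivot_longer(-"drug", names_to = "cell_line", values_to = "value")
}

#' @method glance drug_response_table
#' @export
glance.drug_response_table <- function(x, ...) {
  tibble::tibble(
    n_drugs = nrow(x$values), n_cell_lines = ncol(x$values),
    transform_state = x$transform_state,
    missing_fraction = mean(is.na(x$values)),
    n_all_missing_drugs = length(x$all_missing_drugs)
  )
}

#' Tidy a trained signature into one row per feature-drug cell
#'
#' @param x a `signature_matrix`.
#' @param ... unused.
#' @return Tibble with columns `feature`, `drug`, `r`, `n`, `p`,
#'   `zero_variance`, `filtered`.
#' @method tidy signature_matrix
#' @export
tidy.signature_matrix <- function(x, ...) {
  features <- rownames(x$r)
  drugs <- colnames(x$r)
  tibble::tibble(
    feature = rep(features, times = length(drugs)),
    drug = rep(drugs, each = length(features)),
    r = as.vector(x$r),
    n = as.vector(x$n),
    p = as.vector(x$p),
    zero_variance = as.vector(x$zero_variance_mask),
    filtered = as.vector(x$filtered)
  )
}

#' @method glance signature_matrix
#' @export
glance.signature_matrix <- function(x, ...) {
  active <- !x$zero_variance_mask & !x$filtered
  tibble::tibble(
    n_features = nrow(x$r), n_drugs = ncol(x$r),
    median_n = median(x$n[active]),
    mean_abs_r = mean(abs(x$r[active])),
    n_masked = sum(x$zero_variance_mask), n_filtered = sum(x$filtered)
  )
}

#' Tidy a prediction matrix into one row per drug-sample score
#'
#' @param x a `prediction_matrix`.
#' @param ... unused.
#' @return Tibble with columns `drug`, `sample`, `score`, `n_features`,
#'   `provenance`.
#' @method tidy prediction_matrix
#' @export
tidy.prediction_matrix <- function(x, ...) {
  drugs <- rownames(x$score)
  samples <- colnames(x$score)
  tibble::tibble(
    drug = rep(drugs, times = length(samples)),
    sample = rep(samples, each = length(drugs)),
    score = as.vector(x$score),
    n_features = as.vector(x$n_features),
    provenance = x$provenance
  )
}

#' @method glance prediction_matrix
#' @export
glance.prediction_matrix <- function(x, ...) {
  tibble::tibble(
    n_drugs = nrow(x$score), n_samples = ncol(x$score),
    provenance = x$provenance,
    missing_fraction = mean(is.na(x$score)),
    mean_score = mean(x$score, na.rm = TRUE)
  )
}

#' Tidy an evaluation report into a per-drug table
#'
#' @param x an `evaluation_report` from [evaluate_predictions()].
#' @param ... unused.
#' @return Tibble with columns `drug`, `c_index`, `weight`, `evaluable`.
#' @method tidy evaluation_report
#' @export
tidy.evaluation_report <- function(x, ...) {
  tibble::tibble(
    drug = names(x$per_drug_c),
    c_index = unname(x$per_drug_c),
    weight = unname(x$weights[names(x$per_drug_c)]),
    evaluable = !is.na(x$per_drug_c)
  )
}

#' One-row summary of an evaluation report
#'
#' @param x an `evaluation_report`.
#' @param ... unused.
#' @return One-row tibble: `aggregate_c`, `n_drugs`, `n_evaluable`, and the
#'   permutation-null summary columns (missing when no null was run).
#' @method glance evaluation_report
#' @export
glance.evaluation_report <- function(x, ...) {
  tibble::tibble(
    aggregate_c = x$aggregate_c,
    n_drugs = length(x$per_drug_c),
    n_evaluable = sum(!is.na(x$per_drug_c)),
    null_mean = if (is.null(x$null)) NA_real_ else x$null$null_mean,
    null_sd = if (is.null(x$null)) NA_real_ else x$null$null_sd,
    empirical_p = if (is.null(x$null)) NA_real_ else x$null$empirical_p,
    null_iter = if (is.null(x$null)) NA_integer_ else x$null$n_iter
  )
}
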