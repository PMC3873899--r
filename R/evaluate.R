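# concordance-index evaluation of predicted sensitivity rankings

#' Tie-aware concordance index
#'
#' Over all unordered sample pairs with distinct observed response values:
#' a concordantly ordered pair scores 1, a discordant pair 0, a pair tied in
#' the predictions 0.5; the index is the mean.  Pairs tied in the observed
#' values are excluded from numerator and denominator; if every observed
#' pair is tied the index is defined as 0.5, the chance value (so a drug
#' with constant predictions — or constant observations — scores exactly
#' 0.500).  0.5 is the expectation under random ranking, 1 a perfect
#' ranking.
#'
#' @param predicted numeric vector of predicted scores (higher = predicted
#'   more sensitive).
#' @param observed numeric vector of observed negative-log GI50 values
#'   (higher = more sensitive), same length.
#' @param pair_weight optional function `(obs_i, obs_j) -> weight` giving a
#'   nonnegative weight per evaluable pair (hook for probabilistic,
#'   measurement-noise-aware variants); default weights every pair 1.
#' @return The concordance index in `[0, 1]`, or `NA` if fewer than 2
#'   complete pairs remain.
#' @examples
#' concordance_index(c(1.1, 1.9, 3.2, 3.9), c(1, 2, 3, 4))  # 1
#' concordance_index(c(2, 1, 3, 4), c(1, 2, 3, 4))          # 5/6
#' concordance_index(rep(0, 5), 1:5)                        # 0.5
#' @export
concordance_index <- function(predicted, observed, pair_weight = NULL) {
  ok <- !is.na(predicted) & !is.na(observed)
  predicted <- predicted[ok]
  observed <- observed[ok]
  m <- length(predicted)
  if (m < 2) return(NA_real_)
  ut <- which(upper.tri(matrix(0, m, m)), arr.ind = TRUE)
  d_obs <- observed[ut[, 2]] - observed[ut[, 1]]
  use <- d_obs != 0
  if (!any(use)) return(0.5)
  d_pred <- predicted[ut[, 2]] - predicted[ut[, 1]]
  s <- ifelse(d_pred[use] == 0, 0.5,
              as.numeric(sign(d_pred[use]) == sign(d_obs[use])))
  if (is.null(pair_weight)) return(mean(s))
  w <- mapply(pair_weight, observed[ut[use, 1]], observed[ut[use, 2]])
  if (any(w < 0)) stop("pair weights must be nonnegative", call. = FALSE)
  if (sum(w) == 0) return(NA_real_)
  sum(w * s) / sum(w)
}

#' Weighted average of per-drug concordance indices
#'
#' The aggregate accuracy of a prediction set: the weighted mean of the
#' evaluable per-drug concordance indices.  Default weights are all 1
#' (plain average).
#'
#' @param per_drug_c named numeric vector of per-drug c-indices (`NA` =
#'   unevaluable drug).
#' @param weights named nonnegative weights aligned by drug name, or a single
#'   value recycled; default all 1.
#' @return The weighted mean over evaluable drugs with positive total weight.
#' @export
weighted_average_cindex <- function(per_drug_c, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, length(per_drug_c))
  if (!is.null(names(weights)) && !is.null(names(per_drug_c))) {
    weights <- weights[match(names(per_drug_c), names(weights))]
    weights[is.na(weights)] <- 0
  } else if (length(weights) == 1) {
    weights <- rep(weights, length(per_drug_c))
  }
  if (length(weights) != length(per_drug_c)) {
    stop("weights and per_drug_c lengths differ", call. = FALSE)
  }
  if (any(weights < 0, na.rm = TRUE)) {
    stop("weights must be nonnegative", call. = FALSE)
  }
  ok <- !is.na(per_drug_c)
  if (!any(ok) || sum(weights[ok]) == 0) {
    stop("no evaluable drug with positive weight", call. = FALSE)
  }
  sum(weights[ok] * per_drug_c[ok]) / sum(weights[ok])
}

#' Permutation chance baseline for the aggregate c-index
#'
#' Draws `n_iter` random prediction sets — for every drug, an independent
#' uniform permutation of the sample order — scores each with the tie-aware
#' per-drug c-index and its weighted aggregate, and summarizes the resulting
#' null distribution.  With many iterations the null mean settles around
#' 0.5, the expected score by chance.  When an observed aggregate is given,
#' the one-sided empirical p-value
#' `(#\{null >= observed\} + 1) / (n_iter + 1)` is attached.
#'
#' @param observed a [drug_response_table()] for the evaluation (test) set,
#'   on the negative-log scale.
#' @param n_iter number of permutation iterations (at least 100).
#' @param seed integer seed; the same seed reproduces the summary exactly.
#' @param observed_aggregate optional aggregate c-index of a real prediction
#'   set, for the empirical p-value.
#' @param weights optional per-drug weights (see
#'   [weighted_average_cindex()]).
#' @return A list: `null_mean`, `null_sd`, `empirical_p` (or `NA`), `n_iter`,
#'   `seed`, and the vector of `null_values`.
#' @export
random_baseline <- function(observed, n_iter = 2000, seed = 1,
                            observed_aggregate = NULL, weights = NULL) {
  stopifnot(inherits(observed, "drug_response_table"))
  if (n_iter < 100) stop("n_iter must be at least 100", call. = FALSE)
  set.seed(seed)
  vals <- observed$values
  # precompute, per drug, the sign of the observed difference for evaluable pairs
  per_drug <- lapply(seq_len(nrow(vals)), function(d) {
    y <- vals[d, ]
    y <- y[!is.na(y)]
    m <- length(y)
    if (m < 2) return(NULL)
    ut <- which(upper.tri(matrix(0, m, m)), arr.ind = TRUE)
    d_obs <- y[ut[, 2]] - y[ut[, 1]]
    use <- d_obs != 0
    if (!any(use)) return(list(all_tied = TRUE))
    list(all_tied = FALSE, m = m, i = ut[use, 1], j = ut[use, 2],
         s_obs = sign(d_obs[use]))
  })
  drug_names <- rownames(vals)
  null_values <- vapply(seq_len(n_iter), function(it) {
    cs <- vapply(per_drug, function(pd) {
      if (is.null(pd)) return(NA_real_)
      if (pd$all_tied) return(0.5)
      perm <- sample.int(pd$m)
      d_pred <- perm[pd$j] - perm[pd$i]
      mean(ifelse(d_pred == 0, 0.5, as.numeric(sign(d_pred) == pd$s_obs)))
    }, numeric(1))
    names(cs) <- drug_names
    weighted_average_cindex(cs, weights)
  }, numeric(1))
  emp_p <- if (is.null(observed_aggregate)) NA_real_ else {
    (sum(null_values >= observed_aggregate) + 1) / (n_iter + 1)
  }
  list(null_mean = mean(null_values), null_sd = sd(null_values),
       empirical_p = emp_p, n_iter = n_iter, seed = seed,
       null_values = null_values)
}

#' Evaluate a prediction matrix against observed drug response
#'
#' Computes the per-drug tie-aware c-index of predicted versus observed
#' rankings over the shared cell lines, the weighted aggregate, and
#' optionally a permutation null with empirical p-value.
#'
#' @param pred a `prediction_matrix` (drugs x samples scores).
#' @param observed a [drug_response_table()] on the negative-log scale,
#'   covering (a superset of) the predicted samples.
#' @param weights optional per-drug weights, default all 1.
#' @param null_iter permutation iterations for the chance baseline; 0 skips
#'   the null.
#' @param seed seed for the permutation null.
#' @return An `evaluation_report`: `per_drug_c`, `weights`, `aggregate_c`,
#'   and `null` (list with `null_mean`, `null_sd`, `empirical_p`, `n_iter`,
#'   `seed`, or `NULL`).
#' @export
evaluate_predictions <- function(pred, observed, weights = NULL,
                                 null_iter = 0, seed = 1) {
  stopifnot(inherits(pred, "prediction_matrix"),
            inherits(observed, "drug_response_table"))
  drugs <- intersect(fold_id(rownames(pred$score)), fold_id(rownames(observed$values)))
  if (length(drugs) == 0) stop("no shared drugs", call. = FALSE)
  samples <- intersect(fold_id(colnames(pred$score)), fold_id(colnames(observed$values)))
  if (length(samples) < 2) stop("fewer than 2 shared samples", call. = FALSE)
  p <- pred$score[match(drugs, fold_id(rownames(pred$score))),
                  match(samples, fold_id(colnames(pred$score))), drop = FALSE]
  o <- observed$values[match(drugs, fold_id(rownames(observed$values))),
                       match(samples, fold_id(colnames(observed$values))), drop = FALSE]
  drug_names <- rownames(pred$score)[match(drugs, fold_id(rownames(pred$score)))]
  per_drug_c <- setNames(vapply(seq_along(drugs), function(d) {
    concordance_index(p[d, ], o[d, ])
  }, numeric(1)), drug_names)
  if (is.null(weights)) weights <- setNames(rep(1, length(drugs)), drug_names)
  aggregate_c <- weighted_average_cindex(per_drug_c, weights)
  null <- NULL
  if (null_iter > 0) {
    obs_sub <- drug_response_table(o, transform_state = observed$transform_state)
    null <- random_baseline(obs_sub, n_iter = null_iter, seed = seed,
                            observed_aggregate = aggregate_c, weights = weights)
    null$null_values <- NULL
  }
  structure(
    list(per_drug_c = per_drug_c, weights = weights,
         aggregate_c = aggregate_c, null = null),
    class = "evaluation_report"
  )
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %d drugs (%d evaluable) | aggregate c-index = %.4f\n",
              length(x$per_drug_c), sum(!is.na(x$per_drug_c)), x$aggregate_c))
  if (!is.null(x$null)) {
    cat(sprintf("  permutation null: mean %.4f, sd %.4f, empirical p = %.4g (%d iterations)\n",
                x$null$null_mean, x$null$null_sd, x$null$empirical_p,
                x$null$n_iter))
  }
  invisible(x)
}

#' Write an evaluation report to disk
#'
#' Writes the per-drug table as TSV (`drug`, `c_index`, `weight`) and, next
#' to it, a one-line JSON summary (`aggregate_c`, null summary, iteration
#' count and seed).
#'
#' @param report an `evaluation_report`.
#' @param path output TSV path; the JSON summary goes to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_evaluation <- function(report, path) {
  stopifnot(inherits(report, "evaluation_report"))
  df <- tidy(report)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  summary <- list(aggregate_c = report$aggregate_c)
  if (!is.null(report$null)) {
    summary <- c(summary, report$null[c("null_mean", "null_sd", "empirical_p",
                                        "n_iter", "seed")])
  }
  jsonlite::write_json(summary, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
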