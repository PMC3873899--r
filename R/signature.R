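# the trained model: feature x drug Pearson correlations between expression
# and -log GI50 across training cell lines

new_signature_matrix <- function(r, n, p, zero_variance_mask, filtered) {
  storage.mode(n) <- "integer"
  structure(
    list(r = r, n = n, p = p, zero_variance_mask = zero_variance_mask,
         filtered = filtered),
    class = "signature_matrix"
  )
}

#' @export
print.signature_matrix <- function(x, ...) {
  cat(sprintf("<signature_matrix> %d features x %d drugs\n",
              nrow(x$r), ncol(x$r)))
  cat(sprintf("  masked (zero-variance or n<3) cells: %d | filtered cells: %d\n",
              sum(x$zero_variance_mask), sum(x$filtered)))
  invisible(x)
}

#' @export
dim.signature_matrix <- function(x) dim(x$r)

#' Train a drug sensitivity correlation signature
#'
#' For every (feature, drug) pair, computes the Pearson correlation across
#' training cell lines between the feature's (normalized) expression values
#' and the drug's negative-log growth-inhibition values, using
#' pairwise-complete observations.  A strong positive correlation marks a
#' candidate sensitivity marker, a strong negative one a resistance marker;
#' features with little correlation carry weight near zero in downstream
#' scoring.  Cells with fewer than 3 complete pairs or zero variance in
#' either vector are stored as `r = 0` and flagged in `zero_variance_mask`.
#' Two-sided correlation p-values are attached via [correlation_pvalues()].
#'
#' Expression samples and response cell lines are matched by case-folded
#' identifier; non-overlapping samples are dropped with a message.
#'
#' @param expr an [expression_matrix()] of training cell lines, normalized
#'   (logged + median-centered, or robust z-scored).
#' @param response a [drug_response_table()] with `transform_state = "neglog"`.
#' @return A `signature_matrix` with components `r` (correlations), `n`
#'   (complete-pair counts), `p` (two-sided p-values), `zero_variance_mask`
#'   and `filtered` (all `FALSE` until [filter_by_alpha()]).
#' @examples
#' ex <- simulate_dataset(simulation_config(n_train = 20, n_test = 5,
#'   n_features = c(gene_array = 50), n_drugs = 3, seed = 1))
#' sig <- build_signature(median_center(ex$expression$gene_array),
#'                        ex$response)
#' glance(sig)
#' @export
build_signature <- function(expr, response) {
  stopifnot(inherits(expr, "expression_matrix"),
            inherits(response, "drug_response_table"))
  if (response$transform_state != "neglog") {
    stop("response must be on the negative-log scale; see neglog_response()",
         call. = FALSE)
  }
  samp <- fold_id(colnames(expr$values))
  lines <- fold_id(colnames(response$values))
  shared <- intersect(samp, lines)
  if (length(shared) == 0) {
    stop("no overlapping samples between expression and response", call. = FALSE)
  }
  if (length(shared) < 3) {
    stop(sprintf("only %d overlapping sample(s); at least 3 required",
                 length(shared)), call. = FALSE)
  }
  dropped <- length(samp) - length(shared)
  if (dropped > 0) {
    message(sprintf("build_signature: %d expression sample(s) without response dropped",
                    dropped))
  }
  x <- t(expr$values[, match(shared, samp), drop = FALSE])     # samples x features
  y <- t(response$values[, match(shared, lines), drop = FALSE]) # samples x drugs
  r <- suppressWarnings(cor(x, y, use = "pairwise.complete.obs"))
  n <- crossprod(!is.na(x), !is.na(y))
  mask <- is.na(r) | n < 3
  r[mask] <- 0
  dimnames(r) <- list(rownames(expr$values), rownames(response$values))
  dimnames(n) <- dimnames(r)
  sig <- new_signature_matrix(
    r = r, n = n, p = array(NA_real_, dim(r), dimnames(r)),
    zero_variance_mask = array(mask, dim(r), dimnames(r)),
    filtered = array(FALSE, dim(r), dimnames(r))
  )
  correlation_pvalues(sig)
}

#' Attach two-sided correlation p-values to a signature
#'
#' Uses the t transform `t = r * sqrt((n-2) / (1-r^2))` on `n-2` degrees of
#' freedom; `|r| = 1` gives `p = 0`; masked cells and cells with `n < 3` stay
#' missing.  No multiple-testing correction is applied — the significance
#' cutoffs in [filter_by_alpha()] operate on raw P.
#'
#' @param sig a `signature_matrix` with `r` and `n` populated.
#' @return The signature with its `p` matrix filled in.
#' @export
correlation_pvalues <- function(sig) {
  stopifnot(inherits(sig, "signature_matrix"))
  p <- pearson_pvalue(as.vector(sig$r), as.vector(sig$n))
  p <- matrix(p, nrow(sig$r), ncol(sig$r), dimnames = dimnames(sig$r))
  p[sig$zero_variance_mask] <- NA_real_
  sig$p <- p
  sig
}

#' Zero out signature cells above a significance cutoff
#'
#' Per drug, cells with `p >= alpha` are set to zero: the feature stays in
#' the matrix but contributes nothing to scoring (or is dropped entirely
#' when scoring with `drop_zeroed = TRUE`).  Use [retained_features()] for
#' the per-drug retained counts of a filtered signature.
#'
#' @param sig a `signature_matrix` with p-values populated.
#' @param alpha significance cutoff in `(0, 1]`; `alpha = 1` retains
#'   every unmasked cell.
#' @return The filtered `signature_matrix` (zeroed cells flagged in
#'   `filtered`).
#' @export
filter_by_alpha <- function(sig, alpha) {
  stopifnot(inherits(sig, "signature_matrix"))
  if (!is.numeric(alpha) || length(alpha) != 1 || is.na(alpha) ||
      alpha <= 0 || alpha > 1) {
    stop("alpha must be a single value in (0, 1]", call. = FALSE)
  }
  drop <- !sig$zero_variance_mask & (is.na(sig$p) | sig$p >= alpha)
  sig$r[drop] <- 0
  sig$filtered <- sig$filtered | drop
  sig
}

#' Per-drug retained feature counts after filtering
#'
#' Counts, for each drug, the features still contributing to scoring (not
#' masked, not filtered), and reports the average across drugs with an
#' optional exclusion list for drugs whose counts should not enter the
#' average.
#'
#' @param sig a `signature_matrix`, usually after [filter_by_alpha()].
#' @param exclude drug identifiers to leave out of the reported average.
#' @return A tibble with one row per drug (`drug`, `n_retained`,
#'   `in_average`); the across-drug average is attached as attribute
#'   `"average_retained"` and in `glance()`-style printing.
#' @export
retained_features <- function(sig, exclude = character(0)) {
  stopifnot(inherits(sig, "signature_matrix"))
  active <- !sig$zero_variance_mask & !sig$filtered
  counts <- colSums(active)
  drugs <- colnames(sig$r)
  in_avg <- !fold_id(drugs) %in% fold_id(exclude)
  out <- tibble::tibble(drug = drugs, n_retained = as.integer(counts),
                        in_average = in_avg)
  attr(out, "average_retained") <- mean(counts[in_avg])
  out
}

#' Features recurrently correlated with drug sensitivity
#'
#' Returns the features whose correlation reaches significance `p < alpha`
#' for at least `min_drugs` drugs, in input (matrix) order — the selection
#' used to export marker-by-drug heat maps of the top protein or gene
#' correlates.
#'
#' @param sig a `signature_matrix` with p-values populated.
#' @param alpha significance cutoff (default 0.01).
#' @param min_drugs minimum number of drugs at which a feature must reach
#'   significance (default 2).
#' @return Character vector of feature identifiers.
#' @export
recurrent_features <- function(sig, alpha = 0.01, min_drugs = 2) {
  stopifnot(inherits(sig, "signature_matrix"))
  if (!is.numeric(min_drugs) || length(min_drugs) != 1 || min_drugs < 1) {
    stop("min_drugs must be >= 1", call. = FALSE)
  }
  hits <- rowSums(!is.na(sig$p) & sig$p < alpha)
  rownames(sig$r)[hits >= min_drugs]
}
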