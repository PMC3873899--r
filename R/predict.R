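# scoring test samples against trained signatures

new_prediction_matrix <- function(score, n_features = NULL,
                                  provenance = "unspecified") {
  if (is.null(n_features)) {
    n_features <- array(NA_integer_, dim(score), dimnames(score))
  }
  storage.mode(n_features) <- "integer"
  structure(
    list(score = score, n_features = n_features, provenance = provenance),
    class = "prediction_matrix"
  )
}

#' @export
print.prediction_matrix <- function(x, ...) {
  cat(sprintf("<prediction_matrix> %d drugs x %d samples | provenance=%s\n",
              nrow(x$score), ncol(x$score), x$provenance))
  invisible(x)
}

#' @export
dim.prediction_matrix <- function(x) dim(x$score)

#' Score test samples against a drug sensitivity signature
#'
#' For every (drug, sample) pair, computes the Pearson correlation over the
#' shared features between the drug's signature column and the sample's
#' expression profile — the correlation-of-correlations score.  A high
#' positive score predicts relatively higher sensitivity to the drug.  Shared
#' features are matched case-folded; pairs are pairwise-complete over
#' non-missing features; cells with fewer than 3 usable features or zero
#' variance are missing.
#'
#' By default, zeroed (filtered or masked) signature cells participate as
#' exact zeros, so uninformative features carry weight near zero rather than
#' being excluded; `drop_zeroed = TRUE` excludes them instead, the variant
#' used for restricted top-correlate runs.
#'
#' @param sig a `signature_matrix` from [build_signature()].
#' @param expr_test an [expression_matrix()] of test samples, normalized the
#'   same way as the training expression.
#' @param drop_zeroed drop masked/filtered signature cells from the
#'   correlation instead of letting them participate as zeros.
#' @return A `prediction_matrix` with `score` (drugs x samples, in `[-1, 1]`),
#'   `n_features` used per cell, and `provenance` set to the test platform.
#' @export
score_samples <- function(sig, expr_test, drop_zeroed = FALSE) {
  stopifnot(inherits(sig, "signature_matrix"),
            inherits(expr_test, "expression_matrix"))
  sig_feat <- fold_id(rownames(sig$r))
  test_feat <- fold_id(rownames(expr_test$values))
  shared <- intersect(sig_feat, test_feat)
  if (length(shared) < 3) {
    stop(sprintf(paste0("only %d shared feature(s) between signature (%d features) ",
                        "and test expression (%d features); at least 3 required"),
                 length(shared), length(sig_feat), length(test_feat)),
         call. = FALSE)
  }
  r_use <- sig$r[match(shared, sig_feat), , drop = FALSE]
  if (drop_zeroed) {
    zeroed <- (sig$zero_variance_mask | sig$filtered)[match(shared, sig_feat), ,
                                                      drop = FALSE]
    r_use[zeroed] <- NA_real_
  }
  y <- expr_test$values[match(shared, test_feat), , drop = FALSE]
  score <- suppressWarnings(cor(r_use, y, use = "pairwise.complete.obs"))
  nf <- crossprod(!is.na(r_use), !is.na(y))
  score[nf < 3] <- NA_real_
  dimnames(score) <- list(colnames(sig$r), colnames(expr_test$values))
  dimnames(nf) <- dimnames(score)
  new_prediction_matrix(score, n_features = nf,
                        provenance = expr_test$platform)
}

#' Average predictions across molecular platforms
#'
#' Per (drug, sample) cell, the unweighted mean of the non-missing scores
#' across platforms; platform scores share the common `[-1, 1]` Pearson
#' scale, so no re-ranking or weighting is applied.  Cells missing on every
#' platform stay missing.
#'
#' @param preds a list of `prediction_matrix` objects sharing one drug set;
#'   sample sets must overlap (the union is scored).
#' @return A `prediction_matrix` with `provenance = "averaged"`.
#' @export
average_predictions <- function(preds) {
  if (!is.list(preds) || length(preds) == 0 ||
      !all(vapply(preds, inherits, logical(1), "prediction_matrix"))) {
    stop("preds must be a non-empty list of prediction_matrix objects",
         call. = FALSE)
  }
  drugs <- rownames(preds[[1]]$score)
  for (p in preds[-1]) {
    if (!setequal(fold_id(drugs), fold_id(rownames(p$score)))) {
      stop("platform predictions do not share a common drug set", call. = FALSE)
    }
  }
  samples <- Reduce(union, lapply(preds, function(p) colnames(p$score)))
  acc <- matrix(0, length(drugs), length(samples),
                dimnames = list(drugs, samples))
  cnt <- matrix(0L, length(drugs), length(samples),
                dimnames = list(drugs, samples))
  nf <- matrix(0L, length(drugs), length(samples),
               dimnames = list(drugs, samples))
  for (p in preds) {
    di <- match(fold_id(rownames(p$score)), fold_id(drugs))
    si <- match(colnames(p$score), samples)
    s <- p$score
    ok <- !is.na(s)
    s[!ok] <- 0
    acc[di, si] <- acc[di, si] + s
    cnt[di, si] <- cnt[di, si] + ok
    nfp <- p$n_features
    nfp[is.na(nfp)] <- 0L
    nf[di, si] <- pmax(nf[di, si], nfp)
  }
  score <- acc / cnt
  score[cnt == 0] <- NA_real_
  new_prediction_matrix(score, n_features = nf, provenance = "averaged")
}

#' Restrict a signature and an expression matrix to their shared features
#'
#' Cross-dataset projection (e.g. scoring a tumor cohort, or projecting an
#' RPPA signature onto another panel's drug response) needs both objects on
#' the case-folded identifier intersection, in the same order (the signature's
#' feature order).  The intersection size is reported with a message.
#'
#' @param sig a `signature_matrix`.
#' @param expr_other an [expression_matrix()] from another dataset.
#' @return A list with elements `signature` and `expression`, both restricted
#'   to the shared features.
#' @export
match_features <- function(sig, expr_other) {
  stopifnot(inherits(sig, "signature_matrix"),
            inherits(expr_other, "expression_matrix"))
  sig_feat <- fold_id(rownames(sig$r))
  oth_feat <- fold_id(rownames(expr_other$values))
  shared <- intersect(sig_feat, oth_feat)
  if (length(shared) == 0) {
    stop("no shared features between signature and expression matrix",
         call. = FALSE)
  }
  message(sprintf("match_features: %d shared of %d signature / %d expression features",
                  length(shared), length(sig_feat), length(oth_feat)))
  si <- match(shared, sig_feat)
  oi <- match(shared, oth_feat)
  sig$r <- sig$r[si, , drop = FALSE]
  sig$n <- sig$n[si, , drop = FALSE]
  sig$p <- sig$p[si, , drop = FALSE]
  sig$zero_variance_mask <- sig$zero_variance_mask[si, , drop = FALSE]
  sig$filtered <- sig$filtered[si, , drop = FALSE]
  expr_other$values <- expr_other$values[oi, , drop = FALSE]
  list(signature = sig, expression = expr_other)
}

#' Per-drug concordance of predictions between two platforms
#'
#' For each shared drug, the Spearman rank correlation (average-rank ties)
#' of the two platforms' scores across shared samples; optionally the full
#' drug-by-drug cross-correlation matrix for heat-map export.
#'
#' @param predA,predB `prediction_matrix` objects with shared drugs and at
#'   least 3 shared samples.
#' @param cross return the full drugs(A) x drugs(B) Spearman matrix instead
#'   of the per-drug table.
#' @return A tibble (`drug`, `rho`, `n`) or, with `cross = TRUE`, a numeric
#'   matrix.
#' @export
platform_concordance <- function(predA, predB, cross = FALSE) {
  stopifnot(inherits(predA, "prediction_matrix"),
            inherits(predB, "prediction_matrix"))
  drugs <- intersect(fold_id(rownames(predA$score)), fold_id(rownames(predB$score)))
  samples <- intersect(colnames(predA$score), colnames(predB$score))
  if (length(samples) < 3) {
    stop(sprintf("only %d shared sample(s); at least 3 required", length(samples)),
         call. = FALSE)
  }
  a <- predA$score[match(drugs, fold_id(rownames(predA$score))), samples,
                   drop = FALSE]
  b <- predB$score[match(drugs, fold_id(rownames(predB$score))), samples,
                   drop = FALSE]
  if (cross) {
    m <- suppressWarnings(cor(t(a), t(b), use = "pairwise.complete.obs",
                              method = "spearman"))
    dimnames(m) <- list(rownames(predA$score)[match(drugs, fold_id(rownames(predA$score)))],
                        rownames(predB$score)[match(drugs, fold_id(rownames(predB$score)))])
    return(m)
  }
  rho <- vapply(seq_along(drugs), function(i) {
    ok <- !is.na(a[i, ]) & !is.na(b[i, ])
    if (sum(ok) < 3) return(NA_real_)
    suppressWarnings(cor(a[i, ok], b[i, ok], method = "spearman"))
  }, numeric(1))
  n <- vapply(seq_along(drugs), function(i) sum(!is.na(a[i, ]) & !is.na(b[i, ])),
              integer(1))
  tibble::tibble(
    drug = rownames(predA$score)[match(drugs, fold_id(rownames(predA$score)))],
    rho = rho, n = n
  )
}

#' Association of one drug's prediction scores with a sample covariate
#'
#' Pearson correlation and two-sided t-based p-value between a drug's scores
#' and a per-sample covariate (e.g. a pathway activity score, or a binary
#' subtype indicator coded 0/1 — the point-biserial case).  Values are paired
#' by name when both vectors are named, else by position.
#'
#' @param scores numeric vector of one drug's prediction scores.
#' @param covariate numeric, logical or two-level factor covariate.
#' @return One-row tibble: `r`, `p`, `n`, `zero_variance` (`TRUE` with `r`
#'   and `p` missing when either paired vector is constant).
#' @export
covariate_association <- function(scores, covariate) {
  if (is.factor(covariate)) {
    if (nlevels(droplevels(covariate)) > 2) {
      stop("factor covariates must have exactly 2 levels", call. = FALSE)
    }
    covariate <- as.numeric(covariate == levels(droplevels(covariate))[2])
  }
  covariate <- as.numeric(covariate)
  if (!is.null(names(scores)) && !is.null(names(covariate))) {
    covariate <- covariate[match(names(scores), names(covariate))]
  }
  if (length(scores) != length(covariate)) {
    stop("scores and covariate lengths differ", call. = FALSE)
  }
  ok <- !is.na(scores) & !is.na(covariate)
  if (sum(ok) < 3) {
    stop(sprintf("only %d paired non-missing value(s); at least 3 required",
                 sum(ok)), call. = FALSE)
  }
  x <- scores[ok]
  y <- covariate[ok]
  if (sd(x) == 0 || sd(y) == 0) {
    return(tibble::tibble(r = NA_real_, p = NA_real_, n = sum(ok),
                          zero_variance = TRUE))
  }
  r <- cor(x, y)
  tibble::tibble(r = r, p = pearson_pvalue(r, sum(ok)), n = sum(ok),
                 zero_variance = FALSE)
}
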