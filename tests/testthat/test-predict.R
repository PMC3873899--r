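# scoring test samples, platform averaging, projection, concordance,
# covariate association

sig_from <- function(r_matrix) {
  pair <- list(r = r_matrix)
  corsens:::new_signature_matrix(
    r = r_matrix,
    n = array(10L, dim(r_matrix), dimnames(r_matrix)),
    p = array(0.5, dim(r_matrix), dimnames(r_matrix)),
    zero_variance_mask = array(FALSE, dim(r_matrix), dimnames(r_matrix)),
    filtered = array(FALSE, dim(r_matrix), dimnames(r_matrix))
  )
}

test_that("a test profile equal to a signature column scores +1 / -1", {
  set.seed(1)
  r <- matrix(runif(20, -1, 1), 10, 2,
              dimnames = list(sprintf("g%d", 1:10), c("d1", "d2")))
  sig <- sig_from(r)
  test_vals <- cbind(s1 = r[, "d1"], s2 = -r[, "d1"])
  em <- expression_matrix(test_vals, norm_state = "median_centered")
  pred <- score_samples(sig, em)
  expect_equal(unname(pred$score["d1", "s1"]), 1)
  expect_equal(unname(pred$score["d1", "s2"]), -1)
  expect_equal(pred$provenance, em$platform)
  expect_true(all(abs(pred$score) <= 1 + 1e-12, na.rm = TRUE))
})

test_that("scores with missing features equal a subset Pearson oracle", {
  set.seed(2)
  r <- matrix(rnorm(200), 50, 4,
              dimnames = list(sprintf("g%03d", 1:50), sprintf("d%d", 1:4)))
  sig <- sig_from(r)
  v <- matrix(rnorm(50 * 10), 50, 10,
              dimnames = list(sprintf("g%03d", 1:50), sprintf("s%02d", 1:10)))
  v[runif(500) < 0.1] <- NA  # ~10% missing features per profile
  em <- expression_matrix(v, norm_state = "median_centered")
  pred <- score_samples(sig, em)
  for (d in 1:4) {
    for (s in 1:10) {
      expect_equal(unname(pred$score[d, s]), oracle_pearson(r[, d], v[, s]),
                   tolerance = 1e-12)
      expect_identical(unname(pred$n_features[d, s]),
                       sum(!is.na(r[, d]) & !is.na(v[, s])))
    }
  }
})

test_that("feature matching for scoring is case-folded and guarded", {
  r <- matrix(1:6 + 0, 3, 2, dimnames = list(c("A", "B", "C"), c("d1", "d2")))
  sig <- sig_from(r)
  v <- matrix(rnorm(8), 4, 2, dimnames = list(c("b", "c", "d", "a"), c("s1", "s2")))
  em <- expression_matrix(v, norm_state = "median_centered")
  pred <- score_samples(sig, em)
  ord <- c("a", "b", "c")  # signature order A, B, C
  expect_equal(unname(pred$score[1, 1]),
               oracle_pearson(r[c("A", "B", "C"), 1], v[ord, 1]),
               tolerance = 1e-12)
  few <- expression_matrix(v[1:2, , drop = FALSE], norm_state = "median_centered")
  expect_error(score_samples(sig, few), "at least 3")
})

test_that("drop_zeroed excludes masked and filtered cells from scoring", {
  pair <- make_training_pair(n_features = 40, n_samples = 12, n_drugs = 3,
                             seed = 3)
  sig <- filter_by_alpha(build_signature(pair$expr, pair$resp), 0.2)
  v <- matrix(rnorm(40 * 5), 40, 5,
              dimnames = list(rownames(pair$expr$values), sprintf("t%d", 1:5)))
  em <- expression_matrix(v, norm_state = "median_centered")
  kept <- score_samples(sig, em, drop_zeroed = TRUE)
  for (d in 1:3) {
    use <- !sig$zero_variance_mask[, d] & !sig$filtered[, d]
    for (s in 1:5) {
      want <- if (sum(use) >= 3) oracle_pearson(sig$r[use, d], v[use, s]) else NA_real_
      expect_equal(unname(kept$score[d, s]), want, tolerance = 1e-12)
    }
  }
})

test_that("average_predictions takes the per-cell mean of non-missing scores", {
  mk <- function(vals, provenance) {
    corsens:::new_prediction_matrix(vals, provenance = provenance)
  }
  base <- matrix(c(0.2, 0.4, -0.1, 0.9), 2, 2,
                 dimnames = list(c("d1", "d2"), c("s1", "s2")))
  p1 <- mk(base, "gene_array")
  # identical inputs average to themselves
  expect_equal(average_predictions(list(p1, p1))$score, base)
  other <- base + 0.2
  other["d1", "s1"] <- NA
  p2 <- mk(other, "rnaseq")
  avg <- average_predictions(list(p1, p2))
  expect_equal(unname(avg$score["d2", "s1"]), (0.4 + 0.6) / 2)
  # one platform missing a cell: mean of the remaining values
  expect_equal(unname(avg$score["d1", "s1"]), 0.2)
  expect_equal(avg$provenance, "averaged")
  # averages stay within [min, max] of inputs per cell
  expect_true(all(avg$score >= pmin(base, other, na.rm = TRUE) - 1e-12 &
                  avg$score <= pmax(base, other, na.rm = TRUE) + 1e-12))
  expect_error(average_predictions(list()), "non-empty")
  p3 <- mk(matrix(0, 1, 2, dimnames = list("other_drug", c("s1", "s2"))), "rppa")
  expect_error(average_predictions(list(p1, p3)), "drug set")
})

test_that("match_features restricts both objects to the shared features in order", {
  r <- matrix(rnorm(6), 3, 2, dimnames = list(c("A", "B", "C"), c("d1", "d2")))
  sig <- sig_from(r)
  v <- matrix(rnorm(6), 3, 2, dimnames = list(c("b", "c", "d"), c("s1", "s2")))
  em <- expression_matrix(v, norm_state = "median_centered")
  suppressMessages(out <- match_features(sig, em))
  expect_identical(rownames(out$signature$r), c("B", "C"))
  expect_identical(rownames(out$expression$values), c("b", "c"))
  # identical lists are the identity
  em2 <- expression_matrix(matrix(rnorm(6), 3, 2,
                                  dimnames = list(c("A", "B", "C"), c("s1", "s2"))),
                           norm_state = "median_centered")
  suppressMessages(idt <- match_features(sig, em2))
  expect_identical(idt$signature$r, sig$r)
  # brute-force set intersection preserving the signature's order
  set.seed(4)
  feats1 <- sample(sprintf("G%02d", 1:30), 20)
  feats2 <- sample(tolower(sprintf("G%02d", 1:30)), 20)
  sig2 <- sig_from(matrix(rnorm(20), 20, 1, dimnames = list(feats1, "d1")))
  em3 <- expression_matrix(matrix(rnorm(20), 20, 1,
                                  dimnames = list(feats2, "s1")),
                           norm_state = "median_centered")
  suppressMessages(out2 <- match_features(sig2, em3))
  expect_identical(rownames(out2$signature$r),
                   feats1[toupper(feats1) %in% toupper(feats2)])
  none <- expression_matrix(matrix(1:2 + 0, 2, 1, dimnames = list(c("x", "y"), "s")),
                            norm_state = "median_centered")
  expect_error(suppressMessages(match_features(sig, none)), "no shared")
})

test_that("platform_concordance matches a Pearson-on-average-ranks oracle", {
  set.seed(5)
  a <- matrix(rnorm(40), 4, 10,
              dimnames = list(sprintf("d%d", 1:4), sprintf("s%02d", 1:10)))
  pa <- corsens:::new_prediction_matrix(a, provenance = "gene_array")
  pb <- corsens:::new_prediction_matrix(a, provenance = "rnaseq")
  expect_equal(platform_concordance(pa, pb)$rho, rep(1, 4))
  nb <- corsens:::new_prediction_matrix(-a, provenance = "rnaseq")
  expect_equal(platform_concordance(pa, nb)$rho, rep(-1, 4))
  b <- matrix(rnorm(40), 4, 10, dimnames = dimnames(a))
  b[1, 3] <- b[1, 4]  # introduce a tie
  pbr <- corsens:::new_prediction_matrix(b, provenance = "rnaseq")
  tab <- platform_concordance(pa, pbr)
  for (d in 1:4) {
    expect_equal(tab$rho[d], oracle_spearman(a[d, ], b[d, ]), tolerance = 1e-12)
  }
  cross <- platform_concordance(pa, pbr, cross = TRUE)
  expect_equal(unname(cross[2, 3]), oracle_spearman(a[2, ], b[3, ]),
               tolerance = 1e-12)
  tiny <- corsens:::new_prediction_matrix(a[, 1:2], provenance = "x")
  expect_error(platform_concordance(tiny, tiny), "at least 3")
})

test_that("covariate_association handles numeric and 0/1 covariates", {
  set.seed(6)
  s <- rnorm(12)
  self <- covariate_association(s, s)
  expect_equal(self$r, 1)
  expect_equal(self$p, 0)
  const <- covariate_association(s, rep(2, 12))
  expect_true(const$zero_variance)
  expect_true(is.na(const$r))
  # point-biserial oracle on a random 0/1 indicator
  g <- rep(c(0, 1), 6)
  res <- covariate_association(s, g)
  expect_equal(res$r, oracle_pearson(s, g), tolerance = 1e-12)
  expect_equal(res$p, oracle_cor_pvalue(oracle_pearson(s, g), 12),
               tolerance = 1e-10)
  # factor covariates are accepted as two-level indicators
  fac <- covariate_association(s, factor(ifelse(g == 1, "ER+", "ER-")))
  expect_equal(abs(fac$r), abs(res$r), tolerance = 1e-12)
  expect_error(covariate_association(s[1:2], g[1:2]), "at least 3")
})

test_that("scoring is invariant to positive affine changes of profile or signature", {
  set.seed(7)
  r <- matrix(rnorm(30), 15, 2,
              dimnames = list(sprintf("g%d", 1:15), c("d1", "d2")))
  sig <- sig_from(r)
  v <- matrix(rnorm(30), 15, 2,
              dimnames = list(sprintf("g%d", 1:15), c("s1", "s2")))
  em <- expression_matrix(v, norm_state = "median_centered")
  base <- score_samples(sig, em)
  # shift/scale a test profile
  em2 <- em
  em2$values[, 1] <- 3.7 * em2$values[, 1] + 11
  expect_equal(score_samples(sig, em2)$score, base$score, tolerance = 1e-12)
  # positively rescale a signature column
  sig2 <- sig_from(r %*% diag(c(2.5, 0.3)) + 0)
  dimnames(sig2$r) <- dimnames(r)
  expect_equal(score_samples(sig2, em)$score, base$score, tolerance = 1e-12)
})

test_that("permuting input sample order permutes scores identically", {
  set.seed(8)
  r <- matrix(rnorm(40), 20, 2,
              dimnames = list(sprintf("g%d", 1:20), c("d1", "d2")))
  sig <- sig_from(r)
  v <- matrix(rnorm(100), 20, 5,
              dimnames = list(sprintf("g%d", 1:20), sprintf("s%d", 1:5)))
  em <- expression_matrix(v, norm_state = "median_centered")
  perm <- c(3, 5, 1, 4, 2)
  emp <- expression_matrix(v[, perm], norm_state = "median_centered")
  expect_identical(score_samples(sig, emp)$score,
                   score_samples(sig, em)$score[, perm])
})

test_that("high-sensitivity samples rank above low as noise vanishes", {
  rank_prob <- function(noise_sd, seed) {
    set.seed(seed)
    n_tr <- 30; n_te <- 20
    latent <- rnorm(n_tr + n_te)
    v <- matrix(rnorm(300 * (n_tr + n_te), sd = noise_sd), 300, n_tr + n_te)
    v[1:100, ] <- v[1:100, ] + matrix(latent, 100, n_tr + n_te, byrow = TRUE)
    dimnames(v) <- list(sprintf("g%d", 1:300), sprintf("s%d", seq_len(n_tr + n_te)))
    resp <- matrix(latent + rnorm(n_tr + n_te, sd = noise_sd), 1, n_tr + n_te,
                   dimnames = list("d1", colnames(v)))
    tr <- colnames(v)[1:n_tr]; te <- colnames(v)[-(1:n_tr)]
    sig <- build_signature(
      expression_matrix(v[, tr], norm_state = "median_centered"),
      drug_response_table(resp[, tr, drop = FALSE], transform_state = "neglog"))
    pred <- score_samples(sig, expression_matrix(v[, te],
                                                 norm_state = "median_centered"))
    oracle_cindex(pred$score[1, ], resp[1, te])
  }
  noisy <- mean(vapply(1:5, function(s) rank_prob(1.5, s), numeric(1)))
  clean <- mean(vapply(1:5, function(s) rank_prob(0.1, s), numeric(1)))
  expect_gt(clean, noisy)
  expect_gt(clean, 0.95)
})
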