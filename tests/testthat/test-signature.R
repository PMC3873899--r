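# training the feature x drug correlation signature

expr_one <- function(x) {
  expression_matrix(matrix(x, 1, length(x),
                           dimnames = list("g1", sprintf("s%d", seq_along(x)))),
                    norm_state = "median_centered")
}
resp_one <- function(y) {
  drug_response_table(matrix(y, 1, length(y),
                             dimnames = list("d1", sprintf("s%d", seq_along(y)))),
                      transform_state = "neglog")
}

test_that("perfect monotone linear relationships give r = +/-1", {
  sig <- build_signature(expr_one(1:4), resp_one(1:4))
  expect_equal(unname(sig$r[1, 1]), 1)
  expect_equal(unname(sig$p[1, 1]), 0)
  sig <- build_signature(expr_one(1:4), resp_one(4:1))
  expect_equal(unname(sig$r[1, 1]), -1)
})

test_that("constant features are masked with r = 0 and missing p", {
  sig <- build_signature(expr_one(c(5, 5, 5, 5)), resp_one(c(1, 3, 2, 4)))
  expect_equal(unname(sig$r[1, 1]), 0)
  expect_true(sig$zero_variance_mask[1, 1])
  expect_true(is.na(sig$p[1, 1]))
})

test_that("every signature cell matches the brute-force Pearson oracle", {
  for (seed in 1:3) {
    pair <- make_training_pair(n_features = 50, n_samples = 10, n_drugs = 4,
                               missing_rate = if (seed == 1) 0 else 0.15,
                               seed = seed)
    sig <- build_signature(pair$expr, pair$resp)
    want <- oracle_signature_r(pair$expr$values, pair$resp$values)
    n_want <- (!is.na(pair$expr$values)) %*% t(!is.na(pair$resp$values))
    masked <- is.na(want) | n_want < 3
    want[masked] <- 0
    expect_equal(sig$r, want, tolerance = 1e-12)
    expect_identical(unname(sig$n), unname(matrix(as.integer(n_want),
                                                  nrow(n_want))))
  }
})

test_that("build_signature requires overlapping samples on the neglog scale", {
  pair <- make_training_pair(seed = 5)
  raw <- drug_response_table(abs(pair$resp$values) + 0.1)
  expect_error(build_signature(pair$expr, raw), "negative-log")
  colnames(pair$resp$values) <- paste0("X", colnames(pair$resp$values))
  expect_error(build_signature(pair$expr, pair$resp), "no overlapping")
})

test_that("sample matching between expression and response is case-folded", {
  pair <- make_training_pair(n_features = 5, n_samples = 8, n_drugs = 2, seed = 6)
  lower <- pair$resp
  colnames(lower$values) <- tolower(colnames(lower$values))
  expect_equal(build_signature(pair$expr, lower)$r,
               build_signature(pair$expr, pair$resp)$r)
})

test_that("p-values follow the two-sided t transform and a CDF oracle", {
  # r = 0 on n = 20 is completely unremarkable
  expect_equal(pearson_pvalue_for_test(0, 20), 1)
  # numeric-integration oracle at several (r, n)
  for (case in list(c(0.8, 10), c(0.3, 35), c(-0.6, 18), c(0.95, 5))) {
    expect_equal(pearson_pvalue_for_test(case[1], case[2]),
                 oracle_cor_pvalue(case[1], case[2]), tolerance = 1e-10)
  }
  expect_equal(pearson_pvalue_for_test(1, 5), 0)
  expect_true(is.na(pearson_pvalue_for_test(0.5, 2)))
})

test_that("filter_by_alpha zeroes exactly the cells a threshold scan selects", {
  pair <- make_training_pair(n_features = 60, n_samples = 12, n_drugs = 4,
                             seed = 7)
  sig <- build_signature(pair$expr, pair$resp)
  expect_error(filter_by_alpha(sig, 0), "alpha")
  expect_error(filter_by_alpha(sig, 1.5), "alpha")
  # alpha = 1 is the identity on unmasked cells
  same <- filter_by_alpha(sig, 1)
  expect_identical(same$r, sig$r)
  for (alpha in c(0.05, 0.01, 0.2)) {
    filt <- filter_by_alpha(sig, alpha)
    keep <- !is.na(sig$p) & sig$p < alpha  # brute-force threshold scan
    expect_identical(unname(filt$r[keep]), unname(sig$r[keep]))
    expect_true(all(filt$r[!keep] == 0))
    expect_identical(unname(filt$filtered), unname(!keep & !sig$zero_variance_mask))
    counts <- retained_features(filt)
    expect_identical(counts$n_retained, as.integer(colSums(keep)))
    expect_equal(attr(counts, "average_retained"), mean(colSums(keep)))
  }
  # exclusion list drops named drugs from the average only
  filt <- filter_by_alpha(sig, 0.05)
  keep <- !is.na(sig$p) & sig$p < 0.05
  excl <- retained_features(filt, exclude = "Drug02")
  expect_equal(attr(excl, "average_retained"),
               mean(colSums(keep)[colnames(sig$r) != "Drug02"]))
})

test_that("recurrent_features equals a count-and-threshold oracle", {
  pair <- make_training_pair(n_features = 80, n_samples = 15, n_drugs = 5,
                             seed = 8)
  sig <- build_signature(pair$expr, pair$resp)
  expect_error(recurrent_features(sig, min_drugs = 0), "min_drugs")
  for (alpha in c(0.01, 0.1, 0.5)) {
    for (k in 1:3) {
      hits <- rowSums(!is.na(sig$p) & sig$p < alpha)
      expect_identical(recurrent_features(sig, alpha, k),
                       rownames(sig$r)[hits >= k])
    }
  }
  # a feature significant for exactly one drug is excluded at min_drugs = 2
  one_hit <- rownames(sig$r)[rowSums(sig$p < 0.05) == 1]
  if (length(one_hit) > 0) {
    expect_false(any(one_hit %in% recurrent_features(sig, 0.05, 2)))
  }
})

test_that("signatures are invariant under positive affine feature transforms", {
  pair <- make_training_pair(n_features = 20, n_samples = 10, n_drugs = 3,
                             missing_rate = 0.1, seed = 9)
  sig <- build_signature(pair$expr, pair$resp)
  shifted <- pair$expr
  set.seed(99)
  a <- runif(20, 0.1, 5)
  b <- rnorm(20)
  shifted$values <- pair$expr$values * a + b
  sig2 <- build_signature(shifted, pair$resp)
  expect_equal(sig2$r, sig$r, tolerance = 1e-12)
  # negating a feature row negates its correlations exactly
  neg <- pair$expr
  neg$values[3, ] <- -neg$values[3, ]
  sig3 <- build_signature(neg, pair$resp)
  expect_equal(sig3$r[3, ], -sig$r[3, ])
  expect_equal(sig3$r[-3, ], sig$r[-3, ])
})

test_that("planted driver modules show larger mean |r| that grows with signal", {
  mean_abs_r <- function(rho) {
    set.seed(123)
    n <- 40
    latent <- rnorm(n)
    v <- matrix(rnorm(200 * n), 200, n)
    v[1:50, ] <- rho * matrix(latent, 50, n, byrow = TRUE) +
      sqrt(1 - rho^2) * v[1:50, ]
    dimnames(v) <- list(sprintf("g%d", 1:200), sprintf("s%d", 1:n))
    resp <- matrix(latent, 1, n, dimnames = list("d1", sprintf("s%d", 1:n)))
    sig <- build_signature(
      expression_matrix(v, norm_state = "median_centered"),
      drug_response_table(resp, transform_state = "neglog"))
    c(driver = mean(abs(sig$r[1:50, 1])), null = mean(abs(sig$r[51:200, 1])))
  }
  weak <- mean_abs_r(0.3)
  strong <- mean_abs_r(0.8)
  expect_gt(weak["driver"], weak["null"])
  expect_gt(strong["driver"], strong["null"])
  expect_gt(strong["driver"] - strong["null"], weak["driver"] - weak["null"])
})
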