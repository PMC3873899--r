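# independent brute-force oracles used to check the package implementations;
# each works from first-principles formulas, never the code paths under test

# Pearson correlation over pairwise-complete entries, explicit covariance sums
oracle_pearson <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- unname(x[ok])
  y <- unname(y[ok])
  n <- length(x)
  if (n < 2) return(NA_real_)
  mx <- sum(x) / n
  my <- sum(y) / n
  sxy <- sxx <- syy <- 0
  for (i in seq_len(n)) {
    sxy <- sxy + (x[i] - mx) * (y[i] - my)
    sxx <- sxx + (x[i] - mx)^2
    syy <- syy + (y[i] - my)^2
  }
  if (sxx == 0 || syy == 0) return(NA_real_)
  sxy / sqrt(sxx * syy)
}

# feature x drug correlation matrix by double loop
oracle_signature_r <- function(expr_values, resp_values) {
  out <- matrix(NA_real_, nrow(expr_values), nrow(resp_values),
                dimnames = list(rownames(expr_values), rownames(resp_values)))
  for (f in seq_len(nrow(expr_values))) {
    for (d in seq_len(nrow(resp_values))) {
      out[f, d] <- oracle_pearson(expr_values[f, ], resp_values[d, ])
    }
  }
  out
}

# tie-aware concordance index by explicit enumeration of all unordered pairs
oracle_cindex <- function(pred, obs) {
  ok <- !is.na(pred) & !is.na(obs)
  pred <- unname(pred[ok])
  obs <- unname(obs[ok])
  if (length(pred) < 2) return(NA_real_)
  num <- den <- 0
  for (i in seq_along(pred)) {
    for (j in seq_along(pred)) {
      if (i >= j) next
      if (obs[i] == obs[j]) next
      den <- den + 1
      if (pred[i] == pred[j]) {
        num <- num + 0.5
      } else if ((pred[i] < pred[j]) == (obs[i] < obs[j])) {
        num <- num + 1
      }
    }
  }
  if (den == 0) return(0.5)
  num / den
}

# Spearman rho as Pearson on average ranks
oracle_spearman <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  oracle_pearson(rank(x[ok], ties.method = "average"),
                 rank(y[ok], ties.method = "average"))
}

# two-sided correlation p-value via numeric integration of the t density
oracle_cor_pvalue <- function(r, n) {
  tt <- abs(r) * sqrt((n - 2) / (1 - r^2))
  df <- n - 2
  dens <- function(u) {
    gamma((df + 1) / 2) / (sqrt(df * pi) * gamma(df / 2)) *
      (1 + u^2 / df)^(-(df + 1) / 2)
  }
  2 * stats::integrate(dens, tt, Inf, rel.tol = 1e-12)$value
}

# random expression/response fixture pair on matched cell lines
make_training_pair <- function(n_features = 50, n_samples = 10, n_drugs = 4,
                               missing_rate = 0, seed = 1) {
  set.seed(seed)
  ev <- matrix(rnorm(n_features * n_samples), n_features, n_samples,
               dimnames = list(sprintf("G%03d", seq_len(n_features)),
                               sprintf("S%02d", seq_len(n_samples))))
  rv <- matrix(rnorm(n_drugs * n_samples), n_drugs, n_samples,
               dimnames = list(sprintf("Drug%02d", seq_len(n_drugs)),
                               sprintf("S%02d", seq_len(n_samples))))
  if (missing_rate > 0) {
    ev[runif(length(ev)) < missing_rate] <- NA_real_
    rv[runif(length(rv)) < missing_rate] <- NA_real_
  }
  list(
    expr = expression_matrix(ev, platform = "gene_array",
                             norm_state = "median_centered"),
    resp = drug_response_table(rv, transform_state = "neglog")
  )
}

# write a TSV fixture from a character matrix of tokens
write_fixture <- function(lines, path = tempfile(fileext = ".tsv"),
                          eol = "\n") {
  con <- file(path, open = "wb")
  writeChar(paste0(paste(lines, collapse = eol), eol), con, eos = NULL)
  close(con)
  path
}

# access to the package-internal p-value transform under test
pearson_pvalue_for_test <- function(r, n) corsens:::pearson_pvalue(r, n)
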