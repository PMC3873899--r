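# shared internal helpers

# case-folded identifier key (matching between platforms / response tables is
# case-insensitive throughout)
fold_id <- function(x) toupper(trimws(x))

# check a character vector for duplicates after case folding
assert_unique_folded <- function(ids, what) {
  dup <- unique(ids[duplicated(fold_id(ids))])
  if (length(dup) > 0) {
    stop(sprintf("duplicate %s after case-folding: %s", what,
                 paste(head(fold_id(dup), 5), collapse = ", ")),
         call. = FALSE)
  }
  invisible(ids)
}

# full-precision numeric formatting for TSV output; round-trips doubles exactly
format_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

# parse a character matrix of tokens into numerics; "" and "NA" are missing,
# anything else non-numeric is an error
parse_num <- function(tok, path) {
  miss <- tok == "" | tok == "NA"
  val <- suppressWarnings(as.numeric(tok))
  bad <- !miss & is.na(val)
  if (any(bad)) {
    stop(sprintf("non-numeric value(s) in '%s': %s", path,
                 paste(head(unique(tok[bad]), 5), collapse = ", ")),
         call. = FALSE)
  }
  val[miss] <- NA_real_
  val
}

# two-sided p-value for a Pearson correlation r observed on n pairs, via the
# t transform t = r * sqrt((n-2)/(1-r^2)) on n-2 degrees of freedom
pearson_pvalue <- function(r, n) {
  p <- rep(NA_real_, length(r))
  ok <- !is.na(r) & !is.na(n) & n >= 3
  exact <- ok & abs(r) >= 1
  p[exact] <- 0
  usable <- ok & !exact
  if (any(usable)) {
    tt <- r[usable] * sqrt((n[usable] - 2) / (1 - r[usable]^2))
    p[usable] <- 2 * pt(-abs(tt), df = n[usable] - 2)
  }
  p
}

# seeds derived from a master seed stay within 32-bit integer range
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + k * 104729) %% .Machine$integer.max)
}
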