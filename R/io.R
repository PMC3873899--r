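# flat TSV matrix dialect: UTF-8, tab-separated, header row of sample IDs
# whose first cell may be empty or a label, first column of feature IDs,
# "NA" or empty cell = missing.  Tolerant of CRLF and of a trailing newline.

read_tsv_matrix <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: '%s'", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- sub("\r$", "", lines)
  if (length(lines) > 0 && lines[length(lines)] == "") {
    lines <- lines[-length(lines)]
  }
  if (length(lines) == 0) stop(sprintf("empty file: '%s'", path), call. = FALSE)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  col_ids <- header[-1]
  ncol <- length(col_ids)
  body <- lines[-1]
  row_ids <- character(length(body))
  vals <- matrix(NA_character_, nrow = length(body), ncol = ncol)
  for (i in seq_along(body)) {
    f <- strsplit(body[i], "\t", fixed = TRUE)[[1]]
    # strsplit drops a trailing empty field; restore it
    if (length(f) == ncol && grepl("\t$", body[i])) f <- c(f, "")
    if (length(f) != ncol + 1) {
      stop(sprintf("parse error in '%s' line %d: expected %d fields, got %d",
                   path, i + 1, ncol + 1, length(f)), call. = FALSE)
    }
    row_ids[i] <- f[1]
    if (ncol > 0) vals[i, ] <- f[-1]
  }
  num <- matrix(parse_num(as.vector(vals), path), nrow = length(body), ncol = ncol)
  dimnames(num) <- list(row_ids, col_ids)
  list(values = num, label = header[1])
}

# collapse duplicate (case-folded) row identifiers by the per-column mean of
# non-missing values, keeping the first spelling and first-occurrence order
collapse_duplicate_rows <- function(values) {
  keys <- fold_id(rownames(values))
  if (!anyDuplicated(keys)) return(values)
  dup_keys <- unique(keys[duplicated(keys)])
  warning(sprintf("collapsing %d duplicate feature identifier(s) by mean: %s",
                  length(dup_keys), paste(head(dup_keys, 5), collapse = ", ")),
          call. = FALSE)
  first <- !duplicated(keys)
  out <- values[first, , drop = FALSE]
  for (k in dup_keys) {
    rows <- values[keys == k, , drop = FALSE]
    m <- colMeans(rows, na.rm = TRUE)
    m[!is.finite(m)] <- NA_real_
    out[match(k, keys[first]), ] <- m
  }
  out
}

#' Read an expression matrix from a delimited text file
#'
#' Reads the flat TSV dialect (features in rows, samples in columns, header of
#' sample identifiers whose first cell may be empty or a label; `"NA"` or an
#' empty cell is missing).  Duplicate feature rows (after case folding) are
#' collapsed by their mean with a warning; duplicate sample identifiers are an
#' error; ragged rows raise a parse error naming the offending line.
#'
#' @param path path to the TSV file.
#' @param platform platform label stored on the result.
#' @param norm_state normalization state to declare for the values as read;
#'   use `"logged"` for inputs distributed already on the log scale.
#' @param transpose set `TRUE` if the file stores samples in rows.
#' @return An [expression_matrix()].
#' @seealso [write_matrix()], [read_gct()]
#' @export
read_expression_matrix <- function(path, platform = "unspecified",
                                   norm_state = "raw", transpose = FALSE) {
  raw <- read_tsv_matrix(path)
  values <- raw$values
  if (transpose) values <- t(values)
  if (anyDuplicated(colnames(values))) {
    stop(sprintf("duplicate sample identifiers in '%s'", path), call. = FALSE)
  }
  values <- collapse_duplicate_rows(values)
  expression_matrix(values, platform = platform, norm_state = norm_state)
}

#' Read a drug response table from a delimited text file
#'
#' Drugs in rows and cell lines in columns by default (`transpose = TRUE` for
#' the other orientation).  Non-numeric cells other than the missing markers
#' `"NA"`/empty are a parse error.  A drug row with no non-missing value is
#' accepted and flagged in the returned object's `all_missing_drugs`.
#'
#' @param path path to the TSV file.
#' @param already_neglog `TRUE` if the stored values are already negative-log
#'   concentrations (larger = more sensitive); `FALSE` for raw concentrations.
#' @param transpose set `TRUE` if the file stores cell lines in rows.
#' @return A [drug_response_table()].
#' @export
read_response_table <- function(path, already_neglog = FALSE,
                                transpose = FALSE) {
  raw <- read_tsv_matrix(path)
  values <- raw$values
  if (transpose) values <- t(values)
  drug_response_table(values, transform_state =
                        if (already_neglog) "neglog" else "raw_concentration")
}

#' Read a GCT 1.2 expression file
#'
#' Skips the two GCT header lines and drops the `Description` column; the
#' remainder follows the flat TSV dialect.
#'
#' @inheritParams read_expression_matrix
#' @return An [expression_matrix()].
#' @export
read_gct <- function(path, platform = "unspecified", norm_state = "raw") {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- sub("\r$", "", lines)
  if (length(lines) < 3 || lines[1] != "#1.2") {
    stop(sprintf("'%s' is not a GCT 1.2 file", path), call. = FALSE)
  }
  # drop the (free-text) Description column before numeric parsing
  body <- vapply(lines[-(1:2)], function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    paste(f[-2], collapse = "\t")
  }, character(1), USE.NAMES = FALSE)
  tmp <- tempfile(fileext = ".tsv")
  on.exit(unlink(tmp), add = TRUE)
  writeLines(body, tmp)
  values <- collapse_duplicate_rows(read_tsv_matrix(tmp)$values)
  expression_matrix(values, platform = platform, norm_state = norm_state)
}

write_tsv_matrix <- function(values, path, label = "") {
  con <- file(path, open = "wb")
  on.exit(close(con), add = TRUE)
  writeLines(paste(c(label, colnames(values)), collapse = "\t"), con)
  if (nrow(values) > 0) {
    body <- vapply(seq_len(nrow(values)), function(i) {
      paste(c(rownames(values)[i], format_num(values[i, ])), collapse = "\t")
    }, character(1))
    writeLines(body, con)
  }
  invisible(path)
}

#' Write a matrix container to delimited text
#'
#' Writes the flat TSV dialect with full printed precision so that
#' `read(write(x))` reproduces the values exactly.  Missing values become the
#' token `"NA"`.  Row and column order is preserved deterministically.
#' Signature matrices are written in the long dialect (one row per
#' feature-drug cell with columns `feature, drug, r, n, p, zero_variance,
#' filtered`); see [write_signature()] for the aligned three-matrix dialect.
#'
#' @param x an `expression_matrix`, `drug_response_table`,
#'   `prediction_matrix` or `signature_matrix`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(x, path) UseMethod("write_matrix")

#' @export
write_matrix.expression_matrix <- function(x, path) {
  write_tsv_matrix(x$values, path, label = "feature")
}

#' @export
write_matrix.drug_response_table <- function(x, path) {
  write_tsv_matrix(x$values, path, label = "drug")
}

#' @export
write_matrix.prediction_matrix <- function(x, path) {
  write_tsv_matrix(x$score, path, label = "drug")
}

#' @export
write_matrix.signature_matrix <- function(x, path) {
  write_signature(x, path, format = "long")
}

#' @export
write_matrix.matrix <- function(x, path) {
  write_tsv_matrix(x, path, label = "id")
}

#' Read a prediction matrix (drugs x samples scores) from TSV
#'
#' @param path path to a TSV written by [write_matrix()].
#' @param provenance platform label or `"averaged"`.
#' @return A `prediction_matrix`.
#' @export
read_prediction_matrix <- function(path, provenance = "unspecified") {
  raw <- read_tsv_matrix(path)
  new_prediction_matrix(raw$values, n_features = NULL, provenance = provenance)
}

#' Persist / load a trained signature
#'
#' `format = "wide"` writes three aligned TSV matrices (`<path>.r.tsv`,
#' `<path>.n.tsv`, `<path>.p.tsv`); `format = "long"` writes a single TSV with
#' columns `feature, drug, r, n, p, zero_variance, filtered`.
#'
#' @param sig a `signature_matrix` from [build_signature()].
#' @param path output path (used as a prefix for `"wide"`).
#' @param format `"long"` or `"wide"`.
#' @return `path`, invisibly.
#' @export
write_signature <- function(sig, path, format = c("long", "wide")) {
  format <- match.arg(format)
  if (format == "wide") {
    write_tsv_matrix(sig$r, paste0(path, ".r.tsv"), label = "feature")
    write_tsv_matrix(sig$n + 0.0, paste0(path, ".n.tsv"), label = "feature")
    write_tsv_matrix(sig$p, paste0(path, ".p.tsv"), label = "feature")
    return(invisible(path))
  }
  df <- tidy(sig)
  con <- file(path, open = "wb")
  on.exit(close(con), add = TRUE)
  writeLines(paste(c("feature", "drug", "r", "n", "p", "zero_variance",
                     "filtered"), collapse = "\t"), con)
  if (nrow(df) > 0) {
    writeLines(paste(df$feature, df$drug, format_num(df$r), df$n,
                     format_num(df$p), as.integer(df$zero_variance),
                     as.integer(df$filtered), sep = "\t"), con)
  }
  invisible(path)
}

#' @rdname write_signature
#' @export
read_signature <- function(path, format = c("long", "wide")) {
  format <- match.arg(format)
  if (format == "wide") {
    r <- read_tsv_matrix(paste0(path, ".r.tsv"))$values
    n <- read_tsv_matrix(paste0(path, ".n.tsv"))$values
    p <- read_tsv_matrix(paste0(path, ".p.tsv"))$values
    return(new_signature_matrix(r = r, n = n, p = p,
                                zero_variance_mask = is.na(p) & r == 0,
                                filtered = array(FALSE, dim(r), dimnames(r))))
  }
  df <- utils::read.delim(path, sep = "\t", colClasses = c(
    feature = "character", drug = "character", r = "numeric", n = "integer",
    p = "numeric", zero_variance = "integer", filtered = "integer"),
    check.names = FALSE, na.strings = "NA")
  features <- unique(df$feature)
  drugs <- unique(df$drug)
  shape <- function(col, default) {
    m <- matrix(default, length(features), length(drugs),
                dimnames = list(features, drugs))
    m[cbind(match(df$feature, features), match(df$drug, drugs))] <- col
    m
  }
  new_signature_matrix(
    r = shape(df$r, NA_real_),
    n = shape(df$n, 0L),
    p = shape(df$p, NA_real_),
    zero_variance_mask = shape(df$zero_variance == 1, FALSE),
    filtered = shape(df$filtered == 1, FALSE)
  )
}
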