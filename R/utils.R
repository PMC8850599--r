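# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @noRd
assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

# Split a comma-joined set field into a character vector (empty string -> empty set).
split_tokens <- function(x) {
  if (is.na(x) || !nzchar(x)) return(character())
  trimws(strsplit(x, ",", fixed = TRUE)[[1]])
}

join_tokens <- function(x) paste(x, collapse = ",")

# Strict TSV reader: header required, declared columns required, declared
# numeric columns validated cell-by-cell so errors can name file/line/column.
read_tsv_strict <- function(path, required_cols, numeric_cols = character(),
                            integer_cols = character(), logical_cols = character()) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", quote = "",
                          check.names = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  missing <- setdiff(required_cols, names(df))
  if (length(missing)) {
    stop(sprintf("malformed table '%s': missing column(s) %s",
                 basename(path), paste(missing, collapse = ", ")), call. = FALSE)
  }
  for (col in numeric_cols) {
    vals <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(vals) & nzchar(df[[col]]))
    if (length(bad)) {
      stop(sprintf("malformed numeric field in '%s', line %d, column '%s': %s",
                   basename(path), bad[1] + 1L, col, df[[col]][bad[1]]),
           call. = FALSE)
    }
    df[[col]] <- vals
  }
  for (col in integer_cols) {
    vals <- suppressWarnings(as.integer(df[[col]]))
    bad <- which(is.na(vals) & nzchar(df[[col]]))
    if (length(bad)) {
      stop(sprintf("malformed integer field in '%s', line %d, column '%s': %s",
                   basename(path), bad[1] + 1L, col, df[[col]][bad[1]]),
           call. = FALSE)
    }
    df[[col]] <- vals
  }
  for (col in logical_cols) {
    up <- toupper(trimws(df[[col]]))
    vals <- ifelse(up %in% c("TRUE", "T", "1", "YES"), TRUE,
                   ifelse(up %in% c("FALSE", "F", "0", "NO"), FALSE, NA))
    bad <- which(is.na(vals))
    if (length(bad)) {
      stop(sprintf("malformed logical field in '%s', line %d, column '%s': %s",
                   basename(path), bad[1] + 1L, col, df[[col]][bad[1]]),
           call. = FALSE)
    }
    df[[col]] <- as.logical(vals)
  }
  df
}

write_tsv_plain <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

# Duplicate primary keys -> error listing offenders.
check_primary_key <- function(df, key_cols, table_name) {
  if (!nrow(df)) return(invisible(TRUE))
  keys <- do.call(paste, c(df[key_cols], sep = "\r"))
  dup <- unique(keys[duplicated(keys)])
  if (length(dup)) {
    stop(sprintf("duplicate primary key in table '%s': %s", table_name,
                 paste(gsub("\r", "/", dup), collapse = "; ")), call. = FALSE)
  }
  invisible(TRUE)
}

#' Pooled (n-weighted) mean of subgroup means
#'
#' Recombines subgroup summary statistics into the statistic of the pooled
#' group, e.g. recovering the all-patient mean age from early-stage and
#' late-stage subgroup means and sizes.
#'
#' @param n Integer vector of subgroup sizes.
#' @param means Numeric vector of subgroup means (same length as `n`).
#' @return The n-weighted mean.
#' @examples
#' pooled_mean(c(27, 11), c(65.11, 62.82))
#' @export
pooled_mean <- function(n, means) {
  assert_that(length(n) == length(means) && length(n) > 0,
              "n and means must be non-empty vectors of equal length")
  assert_that(all(n >= 0) && sum(n) > 0, "subgroup sizes must be >= 0 and sum > 0")
  sum(n * means) / sum(n)
}
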