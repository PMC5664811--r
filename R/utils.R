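# internal helpers shared across modules

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Round half away from zero
#'
#' Commercial rounding used for printed percentages (base `round()` rounds
#' half to even, which would print 12.25 as 12.2 rather than 12.3).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded with ties going away from zero.
#' @export
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# write a data.frame as TSV via a temp file + rename, so a failed write
# never leaves a truncated output behind
write_tsv_atomic <- function(df, path) {
  tmp <- tempfile(pattern = basename(path), tmpdir = dirname(path))
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  utils::write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!file.rename(tmp, path)) stop("could not write ", path, call. = FALSE)
  invisible(path)
}

read_tsv_checked <- function(path, required = character()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop(sprintf("%s: missing required column(s): %s",
                 basename(path), paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  df
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
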