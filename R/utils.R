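# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Fixed-point rounding used for MS2 word labels. `base::round()` rounds half
#' to even, which makes word labels depend on the binary representation of the
#' input; half-away-from-zero is bit-stable across platforms.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (>= 0).
#' @return numeric vector rounded to `digits` places.
#' @keywords internal
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Fixed-point label with exactly `digits` decimals, e.g. 100 -> "100.00".
format_mz <- function(x, digits = 2) {
  sprintf(paste0("%.", digits, "f"), round_half_away(x, digits))
}

#' Canonicalize chemical class strings
#'
#' Trims, collapses internal whitespace and case-folds class names so that
#' predicted and literature class sets compare as plain strings.
#'
#' @param x character vector of class names.
#' @return canonicalized character vector (empty strings dropped is up to the
#'   caller; `NA` stays `NA`).
#' @export
#' @examples
#' canonicalize_class(c("  Agarofuran   sesquiterpenoids ", "SIMPLE indole alkaloids"))
canonicalize_class <- function(x) {
  out <- stringr::str_squish(x)
  stringr::str_to_lower(out)
}

# Split a pipe-separated class field into a canonicalized character set.
split_class_set <- function(x) {
  if (length(x) == 0 || is.na(x) || !nzchar(x)) return(character())
  cls <- canonicalize_class(strsplit(x, "|", fixed = TRUE)[[1]])
  unique(cls[nzchar(cls)])
}

# Stop with a named validation error class so tests can assert on it.
validation_error <- function(msg) {
  abort(msg, class = "npscout_validation_error")
}

format_error <- function(msg) {
  abort(msg, class = "npscout_format_error")
}

parameter_error <- function(msg) {
  abort(msg, class = "npscout_parameter_error")
}

# Columns of a feature table that hold per-extract areas, in metadata order.
# sample_only = TRUE restricts to sample_type == "sample" (the scored set).
extract_columns <- function(table, metadata, sample_only = TRUE) {
  fns <- metadata$filename
  if (sample_only) fns <- metadata$filename[metadata$sample_type == "sample"]
  fns[fns %in% names(table)]
}
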