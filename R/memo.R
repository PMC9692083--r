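# MS2 extract vectorization: each extract becomes a vector of counts over
# spectral "words" — binned fragment peaks ("peak@123.45") and neutral losses
# from the precursor ("loss@123.45") — enabling alignment-free comparison of
# extracts. Blank words are removed before the dissimilarity matrix.

#' Default MS2 vectorization parameters
#'
#' @param min_rel_intensity,max_rel_intensity relative-intensity window (base
#'   peak = 1) for retained fragments.
#' @param min_peaks_required spectra with fewer retained fragments contribute
#'   no words.
#' @param losses_from,losses_to neutral-loss window in Da (precursor minus
#'   fragment).
#' @param n_decimal decimal places for word labels (half-away-from-zero
#'   rounding, fixed-point labels).
#' @return a named list of parameters.
#' @export
memo_params <- function(min_rel_intensity = 0.01, max_rel_intensity = 1,
                        min_peaks_required = 10, losses_from = 10,
                        losses_to = 200, n_decimal = 2) {
  if (min_rel_intensity < 0 || min_rel_intensity >= max_rel_intensity ||
      max_rel_intensity > 1) {
    parameter_error("need 0 <= min_rel_intensity < max_rel_intensity <= 1")
  }
  if (losses_from >= losses_to) parameter_error("losses_from must be < losses_to")
  if (n_decimal < 0) parameter_error("n_decimal must be >= 0")
  list(min_rel_intensity = min_rel_intensity,
       max_rel_intensity = max_rel_intensity,
       min_peaks_required = min_peaks_required,
       losses_from = losses_from, losses_to = losses_to, n_decimal = n_decimal)
}

spectrum_words <- function(precursor_mz, peaks, params) {
  if (nrow(peaks) == 0) return(character())
  rel <- peaks$intensity / max(peaks$intensity)
  keep <- rel >= params$min_rel_intensity & rel <= params$max_rel_intensity
  mz <- peaks$mz[keep]
  if (length(mz) < params$min_peaks_required) return(character())
  words <- paste0("peak@", format_mz(mz, params$n_decimal))
  losses <- precursor_mz - mz
  in_window <- losses >= params$losses_from & losses <= params$losses_to
  if (any(in_window)) {
    words <- c(words, paste0("loss@", format_mz(losses[in_window], params$n_decimal)))
  }
  words
}

#' Vectorize MS2 spectra into a word-count matrix
#'
#' Each spectrum is scaled to its base peak, fragments inside the relative
#' intensity window are binned to `n_decimal` places as `peak@` words, and
#' precursor-minus-fragment differences inside the neutral-loss window become
#' `loss@` words. Word occurrences are accumulated per extract. Spectra with
#' fewer than `min_peaks_required` retained fragments, or without a precursor
#' mass, are skipped.
#'
#' @param spectra spectrum tibble ([read_mgf()]) with an added `filename`
#'   column, or without it if `assignment` is given.
#' @param assignment optional tibble (`scan`, `filename`) linking each
#'   spectrum to its extract.
#' @param params vectorization parameters from [memo_params()].
#' @return a word-count tibble: `filename` plus one integer column per word.
#' @export
memo_vectorize <- function(spectra, assignment = NULL, params = memo_params()) {
  if (!is.null(assignment)) {
    spectra <- spectra |>
      select(-any_of("filename")) |>
      inner_join(assignment, by = "scan")
  }
  if (!"filename" %in% names(spectra)) {
    validation_error("spectra must carry a filename column or an assignment table")
  }
  no_precursor <- is.na(spectra$precursor_mz) | spectra$precursor_mz <= 0
  if (any(no_precursor)) {
    inform(paste0("skipping ", sum(no_precursor), " spectra without a precursor mass"))
    spectra <- spectra[!no_precursor, , drop = FALSE]
  }
  extracts <- unique(spectra$filename)
  word_tbl <- spectra |>
    mutate(words = purrr::map2(.data$precursor_mz, .data$peaks,
                               spectrum_words, params = params)) |>
    select("filename", "words") |>
    tidyr::unnest_longer("words", values_to = "word")
  if (nrow(word_tbl) == 0) {
    return(tibble(filename = extracts))
  }
  counts <- word_tbl |>
    dplyr::count(.data$filename, .data$word) |>
    tidyr::pivot_wider(names_from = "word", values_from = "n", values_fill = 0L)
  # keep extracts whose spectra all fell below the peak floor as all-zero rows
  missing_rows <- setdiff(extracts, counts$filename)
  if (length(missing_rows)) {
    counts <- bind_rows(counts, tibble(filename = missing_rows)) |>
      mutate(across(-"filename", ~ tidyr::replace_na(.x, 0L)))
  }
  counts |>
    arrange(match(.data$filename, extracts)) |>
    select("filename", sort(setdiff(names(counts), "filename")))
}

memo_matrix <- function(memo) {
  m <- as.matrix(memo[setdiff(names(memo), "filename")])
  mode(m) <- "numeric"
  rownames(m) <- memo$filename
  m
}

#' Remove background words seen in blank injections
#'
#' Every word with a nonzero count in any blank extract is dropped for all
#' extracts; blank rows are then removed from the matrix.
#'
#' @param memo word-count tibble from [memo_vectorize()].
#' @param blank_filenames filenames of the blank injections.
#' @return the filtered word-count tibble (sample rows only).
#' @export
remove_blank_words <- function(memo, blank_filenames) {
  blanks <- intersect(blank_filenames, memo$filename)
  if (length(blanks) == 0) return(memo)
  m <- memo_matrix(memo)
  blank_support <- colSums(m[blanks, , drop = FALSE]) > 0
  keep_words <- colnames(m)[!blank_support]
  memo |>
    filter(!.data$filename %in% blanks) |>
    select("filename", all_of(keep_words))
}

#' Pairwise dissimilarity between extract word vectors
#'
#' @param memo word-count tibble (after blank-word removal).
#' @param metric dissimilarity index passed to [vegan::vegdist()];
#'   Bray-Curtis by default.
#' @return a symmetric dissimilarity matrix with zero diagonal, one
#'   row/column per extract.
#' @export
memo_distance <- function(memo, metric = "bray") {
  m <- memo_matrix(memo)
  if (nrow(m) < 2) {
    validation_error("at least two extracts are required for a dissimilarity matrix")
  }
  d <- vegan::vegdist(m, method = metric)
  as.matrix(d)
}

#' Read / write a precomputed word-count matrix as CSV
#'
#' Rows are extract filenames, columns are word labels; allows bypassing
#' [memo_vectorize()] with an externally computed matrix.
#'
#' @param path CSV path.
#' @return for the reader, a word-count tibble; the writer returns `path`
#'   invisibly.
#' @export
read_memo_matrix <- function(path) {
  if (!file.exists(path)) format_error(paste0("word-count matrix not found: ", path))
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (names(raw)[1] != "filename") {
    format_error("first column of a word-count matrix must be 'filename'")
  }
  mutate(raw, across(-"filename", as.integer))
}

#' @rdname read_memo_matrix
#' @param memo word-count tibble to write.
#' @export
write_memo_matrix <- function(memo, path) {
  readr::write_csv(memo, path, progress = FALSE)
  invisible(path)
}
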