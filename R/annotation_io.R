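# Readers for the three annotation source tables. Column names vary between
# workflow versions, so each reader takes a canonical-name -> file-column map.

read_mapped_tsv <- function(path, cols, what, integer_cols = "feature_id") {
  if (!file.exists(path)) format_error(paste0(what, " not found: ", path))
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  miss <- setdiff(unname(cols), names(raw))
  if (length(miss)) {
    validation_error(paste0(what, " missing column(s): ", toString(miss)))
  }
  out <- purrr::map(cols, ~ raw[[.x]]) |> as_tibble()
  for (ic in intersect(integer_cols, names(out))) out[[ic]] <- as.integer(out[[ic]])
  out
}

#' Read a GNPS library-annotation TSV
#'
#' @param path path to the TSV.
#' @param cols named character vector mapping the canonical names
#'   `feature_id`, `cosine`, `ppm_error`, `shared_peaks`, `charge`,
#'   `ion_mode` to the file's column names; the default matches the GNPS
#'   feature-based molecular networking export.
#' @return an annotation tibble ready for [clean_gnps()].
#' @export
read_gnps_annotations <- function(path,
                                  cols = c(feature_id = "#Scan#",
                                           cosine = "MQScore",
                                           ppm_error = "MZErrorPPM",
                                           shared_peaks = "SharedPeaks",
                                           charge = "Charge",
                                           ion_mode = "IonMode")) {
  out <- read_mapped_tsv(path, cols, "GNPS annotation table")
  out$ion_mode <- stringr::str_to_lower(stringr::str_sub(out$ion_mode, 1, 3))
  out$ion_mode[out$ion_mode == "pos"] <- "pos"
  out$ion_mode[out$ion_mode == "neg"] <- "neg"
  out
}

#' Read an in-silico spectral-match annotation TSV
#'
#' @param path path to the TSV.
#' @param cols named character vector mapping `feature_id`, `score_final` to
#'   the file's column names.
#' @return a tibble for [merge_annotation_status()].
#' @export
read_isdb_annotations <- function(path,
                                  cols = c(feature_id = "feature_id",
                                           score_final = "score_final")) {
  read_mapped_tsv(path, cols, "in-silico annotation table")
}

#' Read a formula/structure-prediction annotation TSV
#'
#' @param path path to the TSV.
#' @param cols named character vector mapping `feature_id`, `zodiac_score`,
#'   `confidence_score` to the file's column names.
#' @return a tibble for [merge_annotation_status()].
#' @export
read_sirius_annotations <- function(path,
                                    cols = c(feature_id = "feature_id",
                                             zodiac_score = "ZodiacScore",
                                             confidence_score = "ConfidenceScore")) {
  read_mapped_tsv(path, cols, "structure-prediction annotation table")
}
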