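# Quality filtering of spectral-library hits and merging of all annotation
# sources into a per-feature annotated/unannotated status.

#' Filter GNPS spectral-library annotations for quality
#'
#' Retains library hits that pass all of: absolute mass error within
#' `max_ppm_error`, at least `min_shared_peaks` matched fragments, cosine at
#' least `min_cosine`, the requested ionisation mode, and precursor charge at
#' most `max_charge`. All boundaries are inclusive.
#'
#' @param annotations tibble with columns `feature_id`, `cosine`, `ppm_error`,
#'   `shared_peaks`, `charge`, `ion_mode`.
#' @param max_ppm_error maximum absolute mass error in ppm.
#' @param min_shared_peaks minimum number of matched fragment peaks.
#' @param min_cosine minimum modified-cosine score, in \[0, 1\].
#' @param ion_mode ionisation mode to keep, `"pos"` or `"neg"`.
#' @param max_charge maximum precursor charge.
#' @return the retained subset of `annotations`.
#' @export
clean_gnps <- function(annotations, max_ppm_error = 5, min_shared_peaks = 10,
                       min_cosine = 0.6, ion_mode = "pos", max_charge = 2) {
  required <- c("feature_id", "cosine", "ppm_error", "shared_peaks", "charge", "ion_mode")
  miss <- setdiff(required, names(annotations))
  if (length(miss)) {
    validation_error(paste0("GNPS annotations missing column(s): ", toString(miss)))
  }
  keep_mode <- ion_mode
  annotations |>
    filter(
      abs(.data$ppm_error) <= max_ppm_error,
      .data$shared_peaks >= min_shared_peaks,
      .data$cosine >= min_cosine,
      .data$ion_mode == keep_mode,
      .data$charge <= max_charge
    )
}

#' Merge annotation sources into a per-feature status ledger
#'
#' A feature counts as annotated when any source supports it: a GNPS library
#' hit surviving [clean_gnps()], an in-silico spectral match with
#' `score_final >= min_score_final`, or a formula/structure prediction with
#' `zodiac_score >= min_zodiac` and `confidence_score >= min_confidence`
#' (OR-combination; `annotation_preference = 0`). Absent source tables are
#' treated as empty.
#'
#' @param feature_ids integer vector of all feature ids in the table.
#' @param gnps cleaned GNPS annotations (output of [clean_gnps()]), or `NULL`.
#' @param isdb tibble with `feature_id`, `score_final`, or `NULL`.
#' @param sirius tibble with `feature_id`, `zodiac_score`, `confidence_score`,
#'   or `NULL`.
#' @param min_score_final minimum in-silico spectral-match score.
#' @param min_zodiac minimum ZODIAC molecular-formula score, in \[0, 1\].
#' @param min_confidence minimum structure-confidence score, in \[0, 1\].
#' @param annotation_preference source-combination mode; `0` (the default and
#'   only implemented mode) ORs the three sources.
#' @return a tibble with one row per feature: `feature_id`, logical columns
#'   `gnps`, `isdb`, `sirius`, `annotated`, and `annotation_source`
#'   (comma-joined source names, `""` when unannotated).
#' @export
merge_annotation_status <- function(feature_ids, gnps = NULL, isdb = NULL,
                                    sirius = NULL, min_score_final = 0.3,
                                    min_zodiac = 0.9, min_confidence = 0.25,
                                    annotation_preference = 0) {
  if (annotation_preference != 0) {
    parameter_error("only annotation_preference = 0 (OR-combination) is implemented")
  }
  feature_ids <- as.integer(feature_ids)
  gnps_ids <- if (is.null(gnps)) integer() else unique(gnps$feature_id)
  isdb_ids <- if (is.null(isdb)) integer() else
    unique(isdb$feature_id[isdb$score_final >= min_score_final])
  sirius_ids <- if (is.null(sirius)) integer() else
    unique(sirius$feature_id[sirius$zodiac_score >= min_zodiac &
                             sirius$confidence_score >= min_confidence])
  ledger <- tibble(
    feature_id = feature_ids,
    gnps = feature_ids %in% gnps_ids,
    isdb = feature_ids %in% isdb_ids,
    sirius = feature_ids %in% sirius_ids
  )
  ledger |>
    mutate(
      annotated = .data$gnps | .data$isdb | .data$sirius,
      annotation_source = purrr::pmap_chr(
        list(.data$gnps, .data$isdb, .data$sirius),
        function(g, i, s) paste(c("gnps", "isdb", "sirius")[c(g, i, s)], collapse = ",")
      )
    )
}
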