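# Priority Score assembly, the ranked results table and the per-extract
# ion-map export.

#' Combine the four component scores into the Priority Score
#'
#' PS = w_fc * FC + w_lc * LC + w_cc * CC + w_sc * SC, computed on the
#' unrounded components. Extracts are ranked by descending PS; ties are
#' broken by descending FC, then filename.
#'
#' @param components tibble with one row per extract and columns `filename`,
#'   `FC`, `LC`, `CC`, `SC` (an `FS` column, if present, is carried along).
#' @param weights named numeric vector with entries `fc`, `lc`, `cc`, `sc`;
#'   missing entries default to 1.
#' @return `components` with added `PS` and integer `rank`, ordered by rank.
#' @export
compute_ps <- function(components, weights = c(fc = 1, lc = 1, cc = 1, sc = 1)) {
  w <- modifyList(list(fc = 1, lc = 1, cc = 1, sc = 1), as.list(weights))
  for (comp in c("FC", "LC", "CC", "SC")) {
    if (!comp %in% names(components)) {
      validation_error(paste0("missing component column: ", comp))
    }
    bad <- is.na(components[[comp]])
    if (any(bad)) {
      validation_error(paste0("component ", comp, " missing for extract(s): ",
                              toString(components$filename[bad])))
    }
  }
  components |>
    mutate(PS = w$fc * .data$FC + w$lc * .data$LC +
                w$cc * .data$CC + w$sc * .data$SC) |>
    arrange(desc(.data$PS), desc(.data$FC), .data$filename) |>
    mutate(rank = row_number()) |>
    relocate("rank")
}

collapse_class_list <- function(x) {
  vapply(x, function(v) paste(v, collapse = ", "), character(1))
}

#' Assemble the ranked results table
#'
#' One row per scored extract with its taxonomy, all component scores, the
#' literature counts, the new-class names and the Priority Score, ordered by
#' rank.
#'
#' @param fs_fc output of [compute_fs_fc()].
#' @param literature output of [compute_lc()] (includes `rcs`, `rcg`, `LC`).
#' @param cc tibble with `filename` plus the columns of [compute_cc()].
#' @param sc output of [detect_outliers()] (or any tibble with `filename`,
#'   `SC`).
#' @param metadata extract metadata.
#' @param weights Priority Score weights, as in [compute_ps()].
#' @return a tibble with columns `rank`, `filename`, `genus`, `species`,
#'   `organ`, `FS`, `FC`, `LC`, `rcs`, `rcg`, `CC`, `nccs`, `nccg`, `SC`,
#'   `PS` (scores unrounded; see [write_results_table()] for the 2-decimal
#'   display form).
#' @export
build_results_table <- function(fs_fc, literature, cc, sc, metadata,
                                weights = c(fc = 1, lc = 1, cc = 1, sc = 1)) {
  components <- fs_fc |>
    select("filename", "FS", "FC") |>
    left_join(select(literature, "filename", "rcs", "rcg", "LC"), by = "filename") |>
    left_join(
      cc |>
        mutate(nccs = collapse_class_list(.data$new_classes_species),
               nccg = collapse_class_list(.data$new_classes_genus)) |>
        select("filename", "CC", "nccs", "nccg"),
      by = "filename"
    ) |>
    left_join(select(sc, "filename", "SC"), by = "filename")
  ranked <- compute_ps(components, weights)
  ranked |>
    left_join(select(metadata, "filename", "genus", "species", "organ"),
              by = "filename") |>
    select("rank", "filename", "genus", "species", "organ", "FS", "FC", "LC",
           "rcs", "rcg", "CC", "nccs", "nccg", "SC", "PS")
}

#' Write the results table as TSV
#'
#' @param results output of [build_results_table()].
#' @param path output TSV path.
#' @param digits decimal places for the score columns in the file.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(results, path, digits = 2) {
  out <- mutate(results, across(c("FS", "FC", "LC", "PS"), ~ round(.x, digits)))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Per-extract ion map of feature status
#'
#' Categorises every feature detected in one extract as
#' `specific_unannotated` (candidate novel chemistry), `specific_annotated`,
#' or `nonspecific`, with its retention time, m/z and area taken from the
#' pre-filter quantification table so intensities reflect the original data.
#'
#' @param table the feature table BEFORE any intensity/quantile filtering.
#' @param specificity long specificity tibble from [compute_specificity()].
#' @param ledger annotation ledger from [merge_annotation_status()].
#' @param predictions class-prediction tibble, or `NULL`.
#' @param filename the extract to map.
#' @return a tibble with one row per detected feature: `feature_id`, `mz`,
#'   `rt`, `area`, `category`, `adduct`, `npc_class`; classed
#'   `"npscout_ion_map"` so [autoplot()] draws the map.
#' @export
export_ion_map <- function(table, specificity, ledger, predictions = NULL,
                           filename) {
  if (!filename %in% names(table)) {
    validation_error(paste0("unknown extract: ", filename))
  }
  detected <- table[table[[filename]] > 0, , drop = FALSE]
  out <- tibble(
    feature_id = detected$feature_id,
    mz = detected$mz,
    rt = detected$rt,
    area = detected[[filename]],
    adduct = if ("adduct" %in% names(detected)) detected$adduct else NA_character_
  ) |>
    left_join(
      filter(specificity, .data$filename == !!filename) |>
        select("feature_id", "specific"),
      by = "feature_id"
    ) |>
    left_join(select(ledger, "feature_id", "annotated"), by = "feature_id") |>
    mutate(
      specific = dplyr::coalesce(.data$specific, FALSE),
      annotated = dplyr::coalesce(.data$annotated, FALSE),
      category = dplyr::case_when(
        .data$specific & !.data$annotated ~ "specific_unannotated",
        .data$specific & .data$annotated ~ "specific_annotated",
        TRUE ~ "nonspecific"
      )
    )
  if (!is.null(predictions)) {
    best <- predictions |>
      group_by(.data$feature_id) |>
      dplyr::slice_max(.data$npc_probability, n = 1, with_ties = FALSE) |>
      ungroup() |>
      select("feature_id", "npc_class")
    out <- left_join(out, best, by = "feature_id")
  } else {
    out$npc_class <- NA_character_
  }
  out <- select(out, "feature_id", "mz", "rt", "area", "category", "adduct", "npc_class")
  class(out) <- c("npscout_ion_map", class(out))
  attr(out, "extract") <- filename
  out
}

#' Write an ion map as TSV
#'
#' @param ion_map output of [export_ion_map()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_ion_map <- function(ion_map, path) {
  readr::write_tsv(as_tibble(ion_map), path, progress = FALSE)
  invisible(path)
}
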