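# End-to-end pipeline: one call from the raw input tables to the ranked
# results, returning a fitted-object-style result with tidy()/glance()/
# autoplot() methods.

#' Score and rank a library of natural extracts
#'
#' Runs the full prioritization pipeline: ion-identity-network collapsing,
#' optional per-extract intensity and quantile filters, row-wise
#' normalization, feature specificity, annotation-status merging, the four
#' component scores (Feature, Literature, Class, Similarity) and their
#' weighted sum, the Priority Score.
#'
#' @param feature_table aligned feature tibble ([read_feature_table()]).
#' @param metadata extract metadata ([read_extract_metadata()]).
#' @param gnps,isdb,sirius annotation source tibbles, or `NULL` when absent.
#'   `gnps` is raw (it is cleaned with [clean_gnps()] internally).
#' @param predictions class-prediction tibble, or `NULL`.
#' @param occurrence offline taxon-occurrence tibble, or `NULL` (all taxa
#'   then count as unreported).
#' @param spectra MS2 spectrum tibble with a `filename` column, or `NULL`.
#' @param memo precomputed word-count tibble, bypassing vectorization.
#'   When both `spectra` and `memo` are `NULL` the Similarity Component is 0
#'   for every extract, with a message.
#' @param collapse collapse ion identity networks before scoring.
#' @param intensity_min_fraction if non-`NULL`, apply
#'   [apply_intensity_filter()] with this fraction.
#' @param quantile_q if non-`NULL`, apply [apply_quantile_filter()] with this
#'   quantile (after the intensity filter when both are set).
#' @param min_specificity,max_occurrence specificity parameters
#'   ([compute_specificity()]).
#' @param gnps_params named list overriding [clean_gnps()] defaults.
#' @param annotation_params named list overriding
#'   [merge_annotation_status()] thresholds.
#' @param lc_params named list overriding [compute_lc()] parameters.
#' @param min_class_confidence,min_recurrence Class Component thresholds
#'   ([recurrent_classes()]).
#' @param memo_parameters vectorization parameters ([memo_params()]).
#' @param sc_metric dissimilarity index for [memo_distance()].
#' @param detector_params named list overriding [detect_outliers()]
#'   hyperparameters.
#' @param weights Priority Score weights ([compute_ps()]).
#' @param seed seed for the stochastic detector (overridden by
#'   `detector_params$seed` if given).
#' @return an object of class `"npscout_priority"`: a list with the ranked
#'   `results` table, the per-stage intermediates (`fs_fc`, `literature`,
#'   `cc`, `sc`, `specificity`, `ledger`, `table_prefilter`,
#'   `table_scored`, `memo`, `distance`) and the effective `params`.
#' @export
prioritize_extracts <- function(feature_table, metadata,
                                gnps = NULL, isdb = NULL, sirius = NULL,
                                predictions = NULL, occurrence = NULL,
                                spectra = NULL, memo = NULL,
                                collapse = TRUE,
                                intensity_min_fraction = NULL,
                                quantile_q = NULL,
                                min_specificity = 0.90, max_occurrence = 1,
                                gnps_params = list(),
                                annotation_params = list(),
                                lc_params = list(),
                                min_class_confidence = 0.8,
                                min_recurrence = 0.8,
                                memo_parameters = memo_params(),
                                sc_metric = "bray",
                                detector_params = list(),
                                weights = c(fc = 1, lc = 1, cc = 1, sc = 1),
                                seed = 42) {
  metadata <- validate_extract_metadata(metadata)
  validate_feature_table(feature_table)
  table0 <- if (collapse && "iin_id" %in% names(feature_table) &&
                !all(is.na(feature_table$iin_id))) {
    collapse_iin(feature_table)
  } else {
    feature_table
  }
  scored <- table0
  if (!is.null(intensity_min_fraction)) {
    scored <- apply_intensity_filter(scored, intensity_min_fraction)
  }
  if (!is.null(quantile_q)) {
    scored <- apply_quantile_filter(scored, quantile_q)
  }

  # Feature Component
  norm <- normalize_rowwise(scored, metadata)
  specificity <- compute_specificity(norm, metadata, min_specificity, max_occurrence)
  gnps_clean <- if (is.null(gnps)) NULL else
    do.call(clean_gnps, c(list(gnps), gnps_params))
  ledger <- do.call(merge_annotation_status,
                    c(list(feature_ids = scored$feature_id, gnps = gnps_clean,
                           isdb = isdb, sirius = sirius), annotation_params))
  fs_fc <- compute_fs_fc(specificity, ledger, scored, metadata)

  # Literature Component
  samples <- filter(metadata, .data$sample_type == "sample")
  if (is.null(occurrence)) {
    inform("no occurrence table supplied; all taxa treated as unreported (LC = 1)")
    occurrence <- tibble(rank = character(), name = character(),
                         compound_count = integer(), classes = character())
  }
  literature <- do.call(compute_lc,
                        c(list(lookup_taxon(metadata, occurrence)), lc_params))

  # Class Component
  cc <- purrr::map2(samples$filename, seq_len(nrow(samples)), function(fn, i) {
    cls <- recurrent_classes(predictions, scored, fn,
                             min_class_confidence, min_recurrence)
    lit <- literature[literature$filename == fn, ]
    compute_cc(cls, lit$species_classes[[1]], lit$genus_classes[[1]]) |>
      mutate(filename = fn, .before = 1)
  }) |> bind_rows()

  # Similarity Component
  memo_tbl <- NULL
  dist <- NULL
  if (is.null(memo) && !is.null(spectra)) {
    memo <- memo_vectorize(spectra, params = memo_parameters)
  }
  if (!is.null(memo)) {
    blanks <- metadata$filename[metadata$sample_type == "blank"]
    memo_tbl <- remove_blank_words(memo, blanks)
    memo_tbl <- filter(memo_tbl, .data$filename %in% samples$filename)
    dist <- memo_distance(memo_tbl, metric = sc_metric)
    det_args <- modifyList(list(seed = seed), detector_params)
    sc <- do.call(detect_outliers, c(list(dist), det_args))
  } else {
    inform("no spectra or word-count matrix supplied; SC = 0 for all extracts")
    sc <- tibble(filename = samples$filename, lof = FALSE, ocsvm = FALSE,
                 iforest = FALSE, SC = 0L)
  }

  results <- build_results_table(fs_fc, literature, cc, sc, metadata, weights)
  structure(
    list(
      results = results, fs_fc = fs_fc, literature = literature, cc = cc,
      sc = sc, specificity = specificity, ledger = ledger,
      table_prefilter = table0, table_scored = scored,
      memo = memo_tbl, distance = dist, metadata = metadata,
      predictions = predictions,
      params = list(
        min_specificity = min_specificity, max_occurrence = max_occurrence,
        intensity_min_fraction = intensity_min_fraction,
        quantile_q = quantile_q, min_class_confidence = min_class_confidence,
        min_recurrence = min_recurrence, sc_metric = sc_metric,
        weights = weights, seed = seed
      )
    ),
    class = "npscout_priority"
  )
}

#' @export
print.npscout_priority <- function(x, n = 10, ...) {
  cat("Extract prioritization over", nrow(x$results), "extracts\n")
  cat("PS = w_fc*FC + w_lc*LC + w_cc*CC + w_sc*SC, weights:",
      paste(names(x$params$weights), unlist(x$params$weights),
            sep = "=", collapse = " "), "\n\n")
  print(head(x$results, n))
  invisible(x)
}

#' Tidy the per-extract component scores
#'
#' @param x an `npscout_priority` object.
#' @param ... unused.
#' @return the ranked results tibble (one row per extract).
#' @method tidy npscout_priority
#' @export
tidy.npscout_priority <- function(x, ...) {
  x$results
}

#' One-row summary of a prioritization run
#'
#' @param x an `npscout_priority` object.
#' @param ... unused.
#' @return a one-row tibble: extract and feature counts, number of spectral
#'   outliers, the top extract and its Priority Score.
#' @method glance npscout_priority
#' @export
glance.npscout_priority <- function(x, ...) {
  tibble(
    n_extracts = nrow(x$results),
    n_features = nrow(x$table_scored),
    n_outliers = sum(x$results$SC),
    mean_FC = mean(x$results$FC),
    top_extract = x$results$filename[1],
    top_PS = x$results$PS[1]
  )
}

#' Ion map for one extract of a prioritization run
#'
#' Convenience wrapper around [export_ion_map()] using the run's pre-filter
#' table, specificity and annotation ledger.
#'
#' @param x an `npscout_priority` object.
#' @param filename the extract to map.
#' @return an ion-map tibble ([export_ion_map()]).
#' @export
ion_map <- function(x, filename) {
  export_ion_map(x$table_prefilter, x$specificity, x$ledger,
                 x$predictions, filename)
}
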