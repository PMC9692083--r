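# Feature Component: row-wise normalization, per-extract feature specificity
# (with shared specificity across same-species extracts), FS / FC ratios and
# the two optional intensity filters.

area_matrix <- function(table, cols) {
  m <- as.matrix(table[cols])
  rownames(m) <- table$feature_id
  m
}

#' Normalize a feature table row-wise
#'
#' Each feature's areas are divided by that feature's total over the scored
#' (sample) extracts, giving the proportion of its signal found in each
#' extract. Blank and QC columns are excluded from the normalization and
#' dropped from the result. All-zero rows are kept as zeros.
#'
#' @param table a feature-table tibble.
#' @param metadata extract metadata; defines which columns are scored samples.
#' @return a feature-table tibble whose extract columns are row-wise
#'   proportions in \[0, 1\] (rows sum to 1, or 0 for undetected features).
#' @export
normalize_rowwise <- function(table, metadata) {
  cols <- extract_columns(table, metadata, sample_only = TRUE)
  if (length(cols) == 0) validation_error("no sample extract columns to normalize")
  m <- area_matrix(table, cols)
  totals <- rowSums(m)
  scale <- ifelse(totals > 0, totals, 1)
  norm <- m / scale
  out <- table[intersect(FEATURE_CORE_COLS, names(table))]
  bind_cols(out, as_tibble(norm))
}

#' Determine per-extract feature specificity
#'
#' With `max_occurrence = 1` a feature is specific to an extract when at
#' least `min_specificity` of its row-normalized area falls in that extract.
#' With `max_occurrence = N > 1` the concentration may be shared across
#' extracts of the same species: for each species with extract set S, the
#' feature is specific to each of its top-`min(N, |S|)` extracts of S (by
#' normalized area, where it is nonzero) when those top extracts jointly hold
#' at least `min_specificity` of the area. At most one species can satisfy
#' the rule for a given feature whenever `min_specificity > 0.5`.
#'
#' @param norm a row-wise normalized feature table ([normalize_rowwise()]).
#' @param metadata extract metadata (supplies the species grouping).
#' @param min_specificity specificity threshold in (0, 1\].
#' @param max_occurrence maximum number of same-species extracts allowed to
#'   share a feature's signal (N >= 1).
#' @return a long tibble with one row per feature x scored extract:
#'   `feature_id`, `filename`, `specific` (logical).
#' @export
compute_specificity <- function(norm, metadata, min_specificity = 0.90,
                                max_occurrence = 1) {
  if (min_specificity <= 0 || min_specificity > 1) {
    parameter_error("min_specificity must be in (0, 1]")
  }
  if (max_occurrence < 1) parameter_error("max_occurrence must be >= 1")
  cols <- extract_columns(norm, metadata, sample_only = TRUE)
  m <- area_matrix(norm, cols)
  spec <- matrix(FALSE, nrow(m), ncol(m), dimnames = dimnames(m))
  if (max_occurrence == 1) {
    spec <- m >= min_specificity
  } else {
    species_of <- setNames(metadata$species, metadata$filename)[cols]
    for (sp in unique(species_of)) {
      scols <- cols[species_of == sp]
      k <- min(max_occurrence, length(scols))
      sub <- m[, scols, drop = FALSE]
      for (f in seq_len(nrow(sub))) {
        ord <- order(-sub[f, ], seq_along(scols))[seq_len(k)]
        top <- ord[sub[f, ord] > 0]
        if (length(top) && sum(sub[f, top]) >= min_specificity) {
          spec[f, scols[top]] <- TRUE
        }
      }
    }
  }
  as_tibble(spec) |>
    mutate(feature_id = norm$feature_id) |>
    tidyr::pivot_longer(-"feature_id", names_to = "filename", values_to = "specific")
}

#' Compute the Feature Specificity and Feature Component scores
#'
#' For each scored extract, FS is the fraction of its detected features
#' (area > 0) that are specific to it, and FC the fraction that are specific
#' AND carry no structural annotation. Empty extracts (0/0) score 0.
#'
#' @param specificity long specificity tibble from [compute_specificity()].
#' @param ledger annotation status from [merge_annotation_status()].
#' @param table the feature table whose detection status applies (after any
#'   active filters).
#' @param metadata extract metadata.
#' @return a tibble with one row per scored extract: `filename`,
#'   `n_detected`, `n_specific`, `n_specific_unannotated`, `FS`, `FC`.
#' @export
compute_fs_fc <- function(specificity, ledger, table, metadata) {
  cols <- extract_columns(table, metadata, sample_only = TRUE)
  m <- area_matrix(table, cols)
  detected <- as_tibble(m > 0) |>
    mutate(feature_id = table$feature_id) |>
    tidyr::pivot_longer(-"feature_id", names_to = "filename", values_to = "detected")
  status <- select(ledger, "feature_id", "annotated")
  specificity |>
    inner_join(detected, by = c("feature_id", "filename")) |>
    left_join(status, by = "feature_id") |>
    mutate(annotated = dplyr::coalesce(.data$annotated, FALSE)) |>
    group_by(.data$filename) |>
    summarise(
      n_detected = sum(.data$detected),
      n_specific = sum(.data$specific & .data$detected),
      n_specific_unannotated = sum(.data$specific & .data$detected & !.data$annotated),
      .groups = "drop"
    ) |>
    mutate(
      FS = ifelse(.data$n_detected > 0, .data$n_specific / .data$n_detected, 0),
      FC = ifelse(.data$n_detected > 0, .data$n_specific_unannotated / .data$n_detected, 0)
    ) |>
    arrange(match(.data$filename, cols))
}

#' Zero out low-intensity features per extract
#'
#' Sample-wise normalization: each extract column is scaled by its own
#' maximum, and areas below `min_fraction` of that maximum are set to zero.
#' Surviving values are never altered.
#'
#' @param table a feature-table tibble.
#' @param min_fraction fraction of the extract's largest peak below which a
#'   feature is zeroed, in \[0, 1).
#' @return the filtered feature-table tibble.
#' @export
apply_intensity_filter <- function(table, min_fraction = 0.02) {
  if (min_fraction < 0 || min_fraction >= 1) {
    parameter_error("min_fraction must be in [0, 1)")
  }
  cols <- setdiff(names(table), FEATURE_CORE_COLS)
  out <- table
  for (col in cols) {
    v <- out[[col]]
    top <- max(v)
    if (top > 0) v[v / top < min_fraction] <- 0
    out[[col]] <- v
  }
  out
}

#' Zero out features below a per-extract intensity quantile
#'
#' For each extract, the `q`-quantile (linear interpolation) of its nonzero
#' areas is computed; areas strictly below the quantile are set to zero,
#' areas at or above it are retained unchanged.
#'
#' @param table a feature-table tibble.
#' @param q quantile in \[0, 1).
#' @return the filtered feature-table tibble.
#' @export
apply_quantile_filter <- function(table, q = 0.75) {
  if (q < 0 || q >= 1) parameter_error("q must be in [0, 1)")
  cols <- setdiff(names(table), FEATURE_CORE_COLS)
  out <- table
  for (col in cols) {
    v <- out[[col]]
    nz <- v[v > 0]
    if (length(nz)) {
      cut <- quantile(nz, probs = q, type = 7, names = FALSE)
      v[v < cut] <- 0
    }
    out[[col]] <- v
  }
  out
}
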