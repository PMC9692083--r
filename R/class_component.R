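# Class Component: recurrent, confidently predicted chemical classes compared
# to literature class sets by string set subtraction.

#' Find the recurrent confidently predicted classes of an extract
#'
#' A class counts for an extract when enough of the extract's detected
#' features are confidently (probability >= `min_class_confidence`) predicted
#' to belong to it. A `min_recurrence` value of 1 or more is an absolute
#' count ("more than n features", strict); a value in (0, 1) is a fraction
#' of the extract's confidently classified features (also strict).
#'
#' @param predictions tibble with columns `feature_id`, `npc_class`,
#'   `npc_probability` (class-prediction output in the natural-product
#'   classifier ontology, class level).
#' @param table the feature table defining detection (area > 0).
#' @param filename the extract to evaluate.
#' @param min_class_confidence minimum class-prediction probability, \[0, 1\].
#' @param min_recurrence recurrence threshold (count if >= 1, else fraction).
#' @return character vector of canonicalized class names.
#' @export
recurrent_classes <- function(predictions, table, filename,
                              min_class_confidence = 0.8, min_recurrence = 0.8) {
  if (min_recurrence <= 0) parameter_error("min_recurrence must be > 0")
  if (!filename %in% names(table)) {
    validation_error(paste0("unknown extract column: ", filename))
  }
  if (is.null(predictions) || nrow(predictions) == 0) return(character())
  detected_ids <- table$feature_id[table[[filename]] > 0]
  confident <- predictions |>
    filter(
      .data$feature_id %in% detected_ids,
      !is.na(.data$npc_class),
      .data$npc_probability >= min_class_confidence
    ) |>
    mutate(npc_class = canonicalize_class(.data$npc_class))
  if (nrow(confident) == 0) return(character())
  counts <- dplyr::count(confident, .data$npc_class)
  cutoff <- if (min_recurrence >= 1) min_recurrence else min_recurrence * nrow(confident)
  sort(counts$npc_class[counts$n > cutoff])
}

#' Compute the Class Component
#'
#' Compares the extract's recurrent predicted classes to the literature class
#' sets by set subtraction: any class unreported at the species level sets
#' CCs to 0.5, any class unreported at the genus level sets CCg to 0.5, and
#' CC = CCs + CCg. A CC of 1 means the chemistry looks new to both ranks.
#'
#' @param extract_classes character vector of the extract's recurrent classes
#'   ([recurrent_classes()]).
#' @param species_classes,genus_classes character vectors of classes reported
#'   for the species / genus (canonicalized).
#' @return a one-row tibble: `CCs`, `CCg`, `CC`, and list-columns
#'   `new_classes_species`, `new_classes_genus`.
#' @export
compute_cc <- function(extract_classes, species_classes, genus_classes) {
  extract_classes <- unique(canonicalize_class(extract_classes))
  new_sp <- setdiff(extract_classes, canonicalize_class(species_classes))
  new_g <- setdiff(extract_classes, canonicalize_class(genus_classes))
  ccs <- if (length(new_sp)) 0.5 else 0
  ccg <- if (length(new_g)) 0.5 else 0
  tibble(
    CCs = ccs, CCg = ccg, CC = ccs + ccg,
    new_classes_species = list(sort(new_sp)),
    new_classes_genus = list(sort(new_g))
  )
}

#' Read a class-prediction summary table
#'
#' Reads a CANOPUS-style TSV and maps its columns onto the canonical names
#' `feature_id`, `npc_class`, `npc_probability`.
#'
#' @param path path to the TSV.
#' @param cols named character vector mapping canonical names to the file's
#'   column names.
#' @return a class-prediction tibble.
#' @export
read_class_predictions <- function(path,
                                   cols = c(feature_id = "feature_id",
                                            npc_class = "npc_class",
                                            npc_probability = "npc_probability")) {
  if (!file.exists(path)) format_error(paste0("class predictions not found: ", path))
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  miss <- setdiff(unname(cols), names(raw))
  if (length(miss)) {
    validation_error(paste0("class-prediction table missing column(s): ", toString(miss)))
  }
  out <- tibble(
    feature_id = as.integer(raw[[cols[["feature_id"]]]]),
    npc_class = as.character(raw[[cols[["npc_class"]]]]),
    npc_probability = as.numeric(raw[[cols[["npc_probability"]]]])
  )
  ok <- is.na(out$npc_probability) | (out$npc_probability >= 0 & out$npc_probability <= 1)
  if (!all(ok)) validation_error("npc_probability must lie in [0, 1]")
  out
}
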