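# Literature Component: offline per-taxon reported-compound counts and the
# LC score penalising well-studied taxa.

#' Read an offline taxon-occurrence table
#'
#' The table stands in for live natural-product occurrence queries: one row
#' per taxon with its rank, already-resolved name, the number of reported
#' compounds, and the set of reported chemical classes.
#'
#' @param path TSV with columns `rank` (`species`/`genus`/`family`), `name`,
#'   `compound_count`, `classes` (pipe-separated class names, may be empty).
#' @return a validated occurrence tibble.
#' @export
read_occurrence_table <- function(path) {
  if (!file.exists(path)) format_error(paste0("occurrence table not found: ", path))
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("rank", "name", "compound_count", "classes")
  miss <- setdiff(required, names(raw))
  if (length(miss)) {
    validation_error(paste0("occurrence table missing column(s): ", toString(miss)))
  }
  bad <- setdiff(unique(raw$rank), c("species", "genus", "family"))
  if (length(bad)) {
    validation_error(paste0("occurrence rank must be species/genus/family; found: ", toString(bad)))
  }
  if (any(raw$compound_count < 0) || any(raw$compound_count != floor(raw$compound_count))) {
    validation_error("compound_count must be non-negative integers")
  }
  raw$classes <- dplyr::coalesce(as.character(raw$classes), "")
  as_tibble(raw)
}

lookup_rank <- function(occurrence, rank, name) {
  hit <- occurrence[occurrence$rank == rank & occurrence$name == name, ]
  if (nrow(hit) == 0) {
    list(count = 0L, classes = character(), found = FALSE)
  } else {
    list(count = as.integer(hit$compound_count[1]),
         classes = split_class_set(hit$classes[1]), found = TRUE)
  }
}

#' Summarise literature occurrence per extract
#'
#' Joins each scored extract's species, genus and family against the offline
#' occurrence table by exact name match. A taxon absent from the table counts
#' as unreported (0 compounds, no classes) with a warning.
#'
#' @param metadata extract metadata.
#' @param occurrence occurrence tibble from [read_occurrence_table()].
#' @return a tibble with one row per scored extract: `filename`, `rcs`,
#'   `rcg`, `rcf` (reported compound counts at species/genus/family rank) and
#'   list-columns `species_classes`, `genus_classes` of canonicalized class
#'   sets.
#' @export
lookup_taxon <- function(metadata, occurrence) {
  samples <- filter(metadata, .data$sample_type == "sample")
  missing <- character()
  rows <- purrr::pmap(
    list(samples$filename, samples$species, samples$genus, samples$family),
    function(fn, sp, g, fam) {
      s <- lookup_rank(occurrence, "species", sp)
      ge <- lookup_rank(occurrence, "genus", g)
      fa <- lookup_rank(occurrence, "family", fam)
      for (h in list(list(s, sp), list(ge, g), list(fa, fam))) {
        if (!h[[1]]$found) missing <<- c(missing, h[[2]])
      }
      tibble(
        filename = fn, rcs = s$count, rcg = ge$count, rcf = fa$count,
        species_classes = list(s$classes), genus_classes = list(ge$classes)
      )
    }
  )
  if (length(missing)) {
    warn(paste0("taxa absent from occurrence table (treated as unreported): ",
                toString(unique(missing))))
  }
  bind_rows(rows)
}

#' Compute the Literature Component
#'
#' LC starts at 1 (no reported compounds) and subtracts one weighted fraction
#' per taxonomic rank: the reported compound count divided by the
#' user-defined maximum at that rank. With the default equal weights of 1/3
#' and no cap, heavily studied taxa can drive LC below zero.
#'
#' @param summary literature summary from [lookup_taxon()].
#' @param max_sp,max_g,max_f reference maxima for the species, genus and
#'   family counts.
#' @param w_sp,w_g,w_f non-negative weights of the three fractions.
#' @param cap_fractions clip each fraction at 1 before weighting, bounding LC
#'   to \[1 - (w_sp + w_g + w_f), 1\].
#' @return `summary` with an added `LC` column.
#' @export
compute_lc <- function(summary, max_sp = 20, max_g = 100, max_f = 500,
                       w_sp = 1 / 3, w_g = 1 / 3, w_f = 1 / 3,
                       cap_fractions = FALSE) {
  if (min(max_sp, max_g, max_f) <= 0) parameter_error("rank maxima must be > 0")
  if (min(w_sp, w_g, w_f) < 0) parameter_error("weights must be >= 0")
  cap <- if (cap_fractions) function(x) pmin(x, 1) else identity
  summary |>
    mutate(LC = 1 - (w_sp * cap(.data$rcs / max_sp) +
                     w_g * cap(.data$rcg / max_g) +
                     w_f * cap(.data$rcf / max_f)))
}
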