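# Small in-code builders shared across tests.

`%||%` <- function(x, y) if (is.null(x)) y else x

# metadata for n sample extracts (one species each unless species given)
make_metadata <- function(filenames, species = NULL, blanks = character()) {
  species <- species %||% paste("Species", seq_along(filenames))
  dplyr::bind_rows(
    tibble::tibble(
      filename = filenames, species = species,
      genus = paste("Genus", species), family = "Familyaceae",
      organ = "roots", sample_type = "sample"
    ),
    tibble::tibble(
      filename = blanks, species = "none", genus = "none",
      family = "none", organ = "none", sample_type = "blank"
    )
  )
}

# feature table from a plain area matrix (features x extracts)
make_table <- function(areas, filenames = colnames(areas), iin_id = NA_integer_) {
  areas <- as.matrix(areas)
  colnames(areas) <- filenames
  dplyr::bind_cols(
    tibble::tibble(
      feature_id = seq_len(nrow(areas)),
      mz = 100 + seq_len(nrow(areas)),
      rt = seq_len(nrow(areas)) / 10,
      iin_id = rep_len(iin_id, nrow(areas))
    ),
    tibble::as_tibble(areas)
  )
}

# random table + metadata; seeded for reproducibility
random_table <- function(seed, n_features = 50, n_extracts = 4, sparsity = 0.3) {
  withr::with_seed(seed, {
    filenames <- sprintf("ext%02d", seq_len(n_extracts))
    areas <- matrix(stats::runif(n_features * n_extracts, 0, 1e5),
                    n_features, n_extracts, dimnames = list(NULL, filenames))
    areas[stats::runif(length(areas)) < sparsity] <- 0
    list(table = make_table(areas), metadata = make_metadata(filenames))
  })
}

# annotation ledger marking the given ids annotated
make_ledger <- function(feature_ids, annotated_ids = integer()) {
  merge_annotation_status(
    feature_ids,
    isdb = tibble::tibble(feature_id = annotated_ids, score_final = 1)
  )
}
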