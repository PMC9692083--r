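# Deterministic synthetic input bundles with planted ground truth. The
# generator emulates, at desk scale, the structure of a real extract-library
# study: an aligned feature table over a few dozen extracts, partial
# annotation coverage from three sources, class predictions, an offline
# taxon-occurrence table, and per-extract MS2 spectra — with the per-extract
# FS/FC/CC/SC values known by construction.
#
# Planting strategy: every scored extract detects exactly `n_features`
# features — `fraction_specific` of them exclusive to that extract (their
# whole area lives there, normalized share 1 >= any specificity threshold)
# and the rest shared across all extracts with bounded uniform areas (no
# extract can hold >= 90% of a shared feature's area). The planted spectral
# outlier draws its fragments from a disjoint m/z vocabulary with a shifted
# precursor, so its peak AND neutral-loss words are disjoint from the rest.

#' Describe a synthetic input bundle
#'
#' @param n_extracts number of scored (sample) extracts.
#' @param n_features number of features detected per extract.
#' @param extracts_per_species integer vector giving the species layout
#'   (recycled/truncated to `n_extracts`); default one species per extract.
#' @param fraction_specific fraction of each extract's detected features
#'   planted as specific to it.
#' @param fraction_annotated fraction of each extract's specific features
#'   given a passing annotation.
#' @param plant_new_class logical, per extract (recycled): plant a recurrent
#'   confidently predicted class unreported at species and genus rank
#'   (ground-truth CC = 1); otherwise the extract gets no confident class
#'   (CC = 0).
#' @param outlier_index 1-based index of the extract planted as the spectral
#'   outlier, or `NULL` for none.
#' @param n_blanks number of blank injections.
#' @param n_spectra MS2 spectra generated per extract.
#' @param n_small_spectra additional spectra per extract with too few
#'   fragments to pass the word-count floor (they must contribute nothing).
#' @param n_iin_extra number of extra adduct rows added to ion identity
#'   networks (collapsed away without changing ground truth).
#' @param seed integer seed; the same spec and seed give identical bundles.
#' @return a `fixture_spec` list.
#' @export
fixture_spec <- function(n_extracts = 10, n_features = 100,
                         extracts_per_species = 1,
                         fraction_specific = 0.6, fraction_annotated = 0,
                         plant_new_class = TRUE, outlier_index = NULL,
                         n_blanks = 1, n_spectra = 20, n_small_spectra = 0,
                         n_iin_extra = 0, seed = 42) {
  if (n_extracts < 2) validation_error("need at least 2 extracts")
  if (fraction_specific < 0 || fraction_specific > 1 ||
      fraction_annotated < 0 || fraction_annotated > 1) {
    parameter_error("fractions must lie in [0, 1]")
  }
  n_spec <- round(fraction_specific * n_features)
  if (n_spec > n_features) {
    validation_error("more specific features requested than features")
  }
  structure(
    list(n_extracts = n_extracts, n_features = n_features,
         extracts_per_species = extracts_per_species,
         fraction_specific = fraction_specific,
         fraction_annotated = fraction_annotated,
         plant_new_class = rep_len(plant_new_class, n_extracts),
         outlier_index = outlier_index, n_blanks = n_blanks,
         n_spectra = n_spectra, n_small_spectra = n_small_spectra,
         n_iin_extra = n_iin_extra, seed = seed),
    class = "fixture_spec"
  )
}

# species/genus/family layout for the scored extracts
fixture_taxonomy <- function(spec) {
  reps <- rep_len(spec$extracts_per_species, spec$n_extracts)
  species_idx <- rep(seq_along(reps), times = reps)[seq_len(spec$n_extracts)]
  n_species <- max(species_idx)
  organs <- c("roots", "leaves", "stems", "flowers")
  tibble(
    filename = sprintf("extract_%02d", seq_len(spec$n_extracts)),
    species = sprintf("Synthetica specios%02d", species_idx),
    genus = sprintf("Syntheticum%02d", species_idx),
    family = "Syntheticaceae",
    organ = organs[(seq_len(spec$n_extracts) - 1) %% length(organs) + 1],
    sample_type = "sample",
    species_idx = species_idx
  )
}

#' Generate a complete synthetic input bundle
#'
#' @param spec a [fixture_spec()].
#' @return a list with elements `feature_table`, `metadata`, `gnps`, `isdb`,
#'   `sirius`, `predictions`, `occurrence`, `spectra` and `ground_truth` (a
#'   tibble of the planted per-extract `FS`, `FC`, `CC`, `SC`, `rcs`, `rcg`,
#'   `rcf` and the `LC` implied by the default Literature Component
#'   parameters).
#' @export
generate_bundle <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  withr::with_seed(spec$seed, generate_bundle_impl(spec))
}

generate_bundle_impl <- function(spec) {
  tax <- fixture_taxonomy(spec)
  samples <- tax$filename
  blanks <- if (spec$n_blanks > 0) sprintf("blank_%02d", seq_len(spec$n_blanks)) else character()
  metadata <- bind_rows(
    select(tax, -"species_idx"),
    tibble(filename = blanks, species = "none", genus = "none",
           family = "none", organ = "none", sample_type = "blank")
  )

  n_spec <- round(spec$fraction_specific * spec$n_features)
  n_shared <- spec$n_features - n_spec
  n_total <- spec$n_extracts * n_spec + n_shared
  areas <- matrix(0, n_total, length(metadata$filename),
                  dimnames = list(NULL, metadata$filename))
  home <- rep(NA_integer_, n_total)
  if (n_spec > 0) {
    for (e in seq_len(spec$n_extracts)) {
      rows <- (e - 1) * n_spec + seq_len(n_spec)
      home[rows] <- e
      areas[rows, samples[e]] <- stats::runif(n_spec, 5e4, 5e5)
    }
  }
  if (n_shared > 0) {
    shared_rows <- spec$n_extracts * n_spec + seq_len(n_shared)
    # bounded draws: max share 150/(150 + 50*(n-1)) < 0.9 for any n >= 2
    areas[shared_rows, samples] <- matrix(
      stats::runif(n_shared * length(samples), 50, 150) * 1e3,
      n_shared, length(samples)
    )
  }
  feature_table <- tibble(
    feature_id = seq_len(n_total),
    mz = round(stats::runif(n_total, 150, 1200), 4),
    rt = round(stats::runif(n_total, 0.5, 12), 3),
    iin_id = NA_integer_,
    adduct = NA_character_
  ) |> bind_cols(as_tibble(areas))

  # extra adduct rows: same IIN as an existing specific feature, lower area
  if (spec$n_iin_extra > 0 && n_spec > 0) {
    donor_ids <- feature_table$feature_id[!is.na(home)]
    donors <- sample(donor_ids, min(spec$n_iin_extra, length(donor_ids)))
    feature_table$iin_id[match(donors, feature_table$feature_id)] <- donors
    extra <- feature_table[match(donors, feature_table$feature_id), ]
    extra$feature_id <- n_total + seq_along(donors)
    extra$mz <- extra$mz + 21.9819  # sodiated-adduct shift
    extra$adduct <- "[M+Na]+"
    ext_cols <- metadata$filename
    extra[ext_cols] <- extra[ext_cols] / 2
    feature_table$adduct[match(donors, feature_table$feature_id)] <- "[M+H]+"
    feature_table <- bind_rows(feature_table, extra)
  }

  # annotations: fraction_annotated of each extract's specific features get a
  # passing hit, cycling through the three sources; plus sub-threshold decoys
  n_annot <- round(spec$fraction_annotated * n_spec)
  gnps_rows <- list(); isdb_rows <- list(); sirius_rows <- list()
  for (e in seq_len(spec$n_extracts)) {
    ids <- (e - 1) * n_spec + seq_len(n_spec)
    annotated_ids <- ids[seq_len(n_annot)]
    src <- rep_len(c("gnps", "isdb", "sirius"), length(annotated_ids))
    if (any(src == "gnps")) {
      gnps_rows[[length(gnps_rows) + 1]] <- tibble(
        feature_id = annotated_ids[src == "gnps"], cosine = 0.9,
        ppm_error = 1.2, shared_peaks = 15L, charge = 1L, ion_mode = "pos"
      )
    }
    if (any(src == "isdb")) {
      isdb_rows[[length(isdb_rows) + 1]] <- tibble(
        feature_id = annotated_ids[src == "isdb"], score_final = 0.6
      )
    }
    if (any(src == "sirius")) {
      sirius_rows[[length(sirius_rows) + 1]] <- tibble(
        feature_id = annotated_ids[src == "sirius"],
        zodiac_score = 0.97, confidence_score = 0.5
      )
    }
    # decoy: a failing library hit on an unannotated specific feature
    if (n_annot < n_spec) {
      gnps_rows[[length(gnps_rows) + 1]] <- tibble(
        feature_id = ids[n_annot + 1], cosine = 0.35, ppm_error = 8,
        shared_peaks = 4L, charge = 1L, ion_mode = "pos"
      )
    }
  }
  empty_then <- function(x, proto) if (nrow(x) == 0) proto else x
  gnps <- empty_then(bind_rows(gnps_rows), tibble(
    feature_id = integer(), cosine = double(), ppm_error = double(),
    shared_peaks = integer(), charge = integer(), ion_mode = character()
  ))
  isdb <- empty_then(bind_rows(isdb_rows),
                     tibble(feature_id = integer(), score_final = double()))
  sirius <- empty_then(bind_rows(sirius_rows), tibble(
    feature_id = integer(), zodiac_score = double(), confidence_score = double()
  ))

  # class predictions: the planted class covers 5 specific features at high
  # confidence; low-confidence noise on shared features is ignored upstream
  pred_rows <- list()
  planted_class <- sprintf("planted class %02d", seq_len(spec$n_extracts))
  for (e in seq_len(spec$n_extracts)) {
    if (!spec$plant_new_class[e] || n_spec == 0) next
    ids <- (e - 1) * n_spec + seq_len(min(5, n_spec))
    pred_rows[[length(pred_rows) + 1]] <- tibble(
      feature_id = ids, npc_class = planted_class[e], npc_probability = 0.95
    )
  }
  if (n_shared > 0) {
    noise_ids <- spec$n_extracts * n_spec + seq_len(min(3, n_shared))
    pred_rows[[length(pred_rows) + 1]] <- tibble(
      feature_id = noise_ids, npc_class = "Flavonols", npc_probability = 0.5
    )
  }
  predictions <- empty_then(bind_rows(pred_rows), tibble(
    feature_id = integer(), npc_class = character(), npc_probability = double()
  ))

  # offline literature occurrences: counts per taxon, baseline class sets
  base_sp_classes <- "Oleanane triterpenoids|Quinoline alkaloids"
  base_g_classes <- paste0(base_sp_classes, "|Cinnamic acid esters")
  sp_tab <- distinct(tax, .data$species, .data$genus)
  rcs <- sample(0:20, nrow(sp_tab), replace = TRUE)
  rcg <- rcs + sample(0:400, nrow(sp_tab), replace = TRUE)
  rcf <- sample(500:5000, 1)
  occurrence <- bind_rows(
    tibble(rank = "species", name = sp_tab$species, compound_count = rcs,
           classes = base_sp_classes),
    tibble(rank = "genus", name = sp_tab$genus, compound_count = rcg,
           classes = base_g_classes),
    tibble(rank = "family", name = "Syntheticaceae", compound_count = rcf,
           classes = base_g_classes)
  )

  spectra <- fixture_spectra(spec, samples, blanks)

  lit <- tibble(
    filename = samples,
    rcs = rcs[tax$species_idx], rcg = rcg[tax$species_idx], rcf = rcf
  )
  ground_truth <- lit |>
    mutate(
      FS = n_spec / spec$n_features,
      FC = (n_spec - n_annot) / spec$n_features,
      CC = ifelse(spec$plant_new_class, 1, 0),
      SC = as.integer(seq_len(spec$n_extracts) %in% (spec$outlier_index %||% integer())),
      LC = 1 - (.data$rcs / 20 + .data$rcg / 100 + .data$rcf / 500) / 3
    )

  list(feature_table = feature_table, metadata = metadata, gnps = gnps,
       isdb = isdb, sirius = sirius, predictions = predictions,
       occurrence = occurrence, spectra = spectra,
       ground_truth = ground_truth, spec = spec)
}

# Per-extract MS2 spectra. The non-outlier extracts share a common core
# vocabulary — the i-th spectrum of every extract carries the same core
# fragment set plus a couple of extract-specific random fragments — so the
# set forms one spectrally homogeneous group, as extracts of related taxa
# do. The planted outlier draws from a disjoint m/z range on a shifted
# label grid with a shifted precursor, making its peak AND loss words
# disjoint. Vocabulary pools are laid out so that blank-word removal leaves
# this structure intact.
fixture_spectra <- function(spec, samples, blanks) {
  common_pool <- seq(100, 400, by = 2) + 0.10   # peak words *.10
  outlier_pool <- seq(600, 900, by = 2) + 0.15  # disjoint range and grid
  blank_pool <- seq(420, 440, by = 1) + 0.10
  rows <- list()
  scan <- 0L
  make_spectrum <- function(filename, frags, precursor) {
    scan <<- scan + 1L
    tibble(
      scan = scan, filename = filename, precursor_mz = precursor,
      peaks = list(tibble(mz = sort(frags),
                          intensity = stats::runif(length(frags), 20, 100)))
    )
  }
  # the s-th spectrum of every extract shares this core fragment set
  core_frags <- function(pool, s) {
    pool[((s - 1) * 8 + seq_len(8) - 1) %% length(pool) + 1]
  }
  for (e in seq_along(samples)) {
    is_outlier <- e %in% (spec$outlier_index %||% integer())
    pool <- if (is_outlier) outlier_pool else common_pool
    precursor <- if (is_outlier) 950.00 else 450.00
    for (s in seq_len(spec$n_spectra)) {
      frags <- c(core_frags(pool, s), sample(pool, 2), sample(blank_pool, 2))
      rows[[length(rows) + 1]] <- make_spectrum(samples[e], frags, precursor)
    }
    for (s in seq_len(spec$n_small_spectra)) {
      rows[[length(rows) + 1]] <-
        make_spectrum(samples[e], sample(pool, 5), precursor)
    }
  }
  for (b in blanks) {
    for (s in seq_len(max(spec$n_spectra %/% 2, 1))) {
      # precursor below fragment+10 Da: blanks emit no loss words
      rows[[length(rows) + 1]] <- make_spectrum(b, sample(blank_pool, 12), 425.00)
    }
  }
  bind_rows(rows)
}

#' Write a synthetic bundle to disk in its external formats
#'
#' Emits exactly the files the readers consume: an MZmine-dialect feature
#' CSV, metadata TSV, the three annotation TSVs (GNPS export column names),
#' a class-prediction TSV, the occurrence TSV and one MGF per extract under
#' `spectra/`.
#'
#' @param bundle output of [generate_bundle()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_feature_table(bundle$feature_table, file.path(dir, "feature_table.csv"),
                      mzmine_headers = TRUE)
  readr::write_tsv(bundle$metadata, file.path(dir, "metadata.tsv"), progress = FALSE)
  gnps_out <- bundle$gnps |>
    rename(`#Scan#` = "feature_id", MQScore = "cosine", MZErrorPPM = "ppm_error",
           SharedPeaks = "shared_peaks", Charge = "charge", IonMode = "ion_mode")
  readr::write_tsv(gnps_out, file.path(dir, "gnps_annotations.tsv"), progress = FALSE)
  readr::write_tsv(bundle$isdb, file.path(dir, "isdb_annotations.tsv"), progress = FALSE)
  sirius_out <- rename(bundle$sirius, ZodiacScore = "zodiac_score",
                       ConfidenceScore = "confidence_score")
  readr::write_tsv(sirius_out, file.path(dir, "sirius_annotations.tsv"), progress = FALSE)
  readr::write_tsv(bundle$predictions, file.path(dir, "class_predictions.tsv"),
                   progress = FALSE)
  readr::write_tsv(bundle$occurrence, file.path(dir, "occurrences.tsv"), progress = FALSE)
  spec_dir <- file.path(dir, "spectra")
  dir.create(spec_dir, showWarnings = FALSE)
  for (fn in unique(bundle$spectra$filename)) {
    write_mgf(filter(bundle$spectra, .data$filename == fn),
              file.path(spec_dir, paste0(fn, ".mgf")))
  }
  invisible(dir)
}
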