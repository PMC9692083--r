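# Reading, validation and IIN collapsing of the tabular / spectral inputs.
#
# A feature table is a plain tibble: the columns `feature_id`, `mz`, `rt`
# (plus optional `iin_id`, `adduct`) describe the aligned feature, and every
# remaining column is a per-extract peak area (or height) named by the
# metadata filename. All module functions share this convention.

FEATURE_CORE_COLS <- c("feature_id", "mz", "rt", "iin_id", "adduct")

# MZmine-style header aliases -> canonical names
.mzmine_aliases <- c(
  "row id" = "feature_id", "id" = "feature_id",
  "row m/z" = "mz", "mz" = "mz", "m/z" = "mz",
  "row retention time" = "rt", "rt" = "rt", "retention time" = "rt",
  "correlation group id" = "iin_id", "iin_id" = "iin_id",
  "best ion" = "adduct", "adduct" = "adduct"
)

#' Read an aligned feature quantification table
#'
#' Parses an MZmine-style aligned feature CSV: one row per feature with its
#' id, m/z and retention time, and one peak-area (or height) column per
#' extract. Both the long MZmine header dialect (`row ID`, `row m/z`,
#' `row retention time`, `correlation group ID`, `best ion`) and the plain
#' dialect (`id`, `mz`, `rt`, `iin_id`, `adduct`) are accepted. Extract
#' column names are normalized by stripping `.mzML` / `.mzXML` and
#' `" Peak area"` / `" Peak height"` suffixes so they match metadata
#' filenames.
#'
#' @param path path to the CSV file.
#' @param dialect input dialect; only `"mzmine_csv"` is implemented.
#' @param metadata optional extract metadata (see [read_extract_metadata()]);
#'   when given, the extract columns are checked against its filenames.
#' @return a feature-table tibble (columns `feature_id`, `mz`, `rt`, optional
#'   `iin_id` and `adduct`, then one numeric area column per extract).
#' @export
read_feature_table <- function(path, dialect = c("mzmine_csv"), metadata = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) format_error(paste0("feature table not found: ", path))
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  nm <- names(raw)
  lowered <- stringr::str_to_lower(stringr::str_squish(nm))
  canon <- unname(.mzmine_aliases[lowered])
  is_core <- !is.na(canon)
  names(raw)[is_core] <- canon[is_core]
  # extract columns: strip quantification suffixes and file extensions
  ext_cols <- nm[!is_core]
  cleaned <- stringr::str_remove(ext_cols, "\\s*Peak (area|height)\\s*$")
  cleaned <- stringr::str_remove(cleaned, "\\.(mzML|mzXML)$")
  names(raw)[!is_core] <- cleaned
  for (required in c("feature_id", "mz", "rt")) {
    if (!required %in% names(raw)) {
      format_error(paste0("feature table is missing the '", required, "' column"))
    }
  }
  raw$feature_id <- as.integer(raw$feature_id)
  if ("iin_id" %in% names(raw)) raw$iin_id <- as.integer(raw$iin_id)
  out <- as_tibble(raw)
  validate_feature_table(out, metadata)
  out
}

#' Validate a feature table
#'
#' Checks the feature-table invariants: unique `feature_id`, positive `mz`,
#' non-negative `rt`, non-negative areas, and (when metadata is supplied)
#' that the extract columns are exactly the metadata filenames.
#'
#' @inheritParams read_feature_table
#' @param table a feature-table tibble.
#' @return `table`, invisibly.
#' @export
validate_feature_table <- function(table, metadata = NULL) {
  if (anyDuplicated(table$feature_id)) {
    validation_error("duplicate feature_id in feature table")
  }
  if (any(table$mz <= 0)) validation_error("feature m/z must be > 0")
  if (any(table$rt < 0)) validation_error("feature rt must be >= 0")
  area_cols <- setdiff(names(table), FEATURE_CORE_COLS)
  if (length(area_cols) == 0) {
    format_error("feature table has no per-extract area columns")
  }
  areas <- as.matrix(table[area_cols])
  if (!is.numeric(areas)) validation_error("area columns must be numeric")
  if (any(is.na(areas))) validation_error("area columns contain missing values")
  if (any(areas < 0)) validation_error("negative peak area in feature table")
  if (!is.null(metadata)) {
    missing_cols <- setdiff(metadata$filename, area_cols)
    extra_cols <- setdiff(area_cols, metadata$filename)
    if (length(missing_cols) || length(extra_cols)) {
      validation_error(paste0(
        "extract columns do not match metadata filenames",
        if (length(missing_cols)) paste0("; missing: ", toString(missing_cols)) else "",
        if (length(extra_cols)) paste0("; unexpected: ", toString(extra_cols)) else ""
      ))
    }
  }
  invisible(table)
}

#' Read the extract metadata table
#'
#' @param path path to a TSV or CSV file with columns `filename`, `species`,
#'   `genus`, `family`, `organ`, `sample_type` (`sample`, `blank` or `QC`).
#' @return a tibble of validated extract records.
#' @export
read_extract_metadata <- function(path) {
  if (!file.exists(path)) format_error(paste0("metadata not found: ", path))
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE, progress = FALSE)
  validate_extract_metadata(as_tibble(raw))
}

#' @rdname read_extract_metadata
#' @param metadata a metadata tibble to validate.
#' @export
validate_extract_metadata <- function(metadata) {
  required <- c("filename", "species", "genus", "family", "sample_type")
  miss <- setdiff(required, names(metadata))
  if (length(miss)) {
    validation_error(paste0("metadata is missing column(s): ", toString(miss)))
  }
  if (nrow(metadata) == 0) validation_error("metadata table is empty")
  if (anyDuplicated(metadata$filename)) {
    validation_error("duplicate filename in metadata")
  }
  bad <- setdiff(unique(metadata$sample_type), c("sample", "blank", "QC"))
  if (length(bad)) {
    validation_error(paste0("sample_type must be sample/blank/QC; found: ", toString(bad)))
  }
  if (!"organ" %in% names(metadata)) metadata$organ <- NA_character_
  metadata
}

#' Collapse ion identity networks to one row per neutral molecule
#'
#' Features grouped by an ion identity network (IIN) id — adducts and
#' in-source fragments of one molecule — are merged into a single row. The
#' per-extract area of the group is the element-wise maximum over its members
#' (the most representative ion-adduct); the representative `feature_id`,
#' `mz`, `rt` and `adduct` come from the member with the greatest summed area
#' (ties broken by lowest `feature_id`). Features without an `iin_id` pass
#' through unchanged.
#'
#' @param table a feature-table tibble.
#' @return a feature-table tibble with one row per IIN group.
#' @export
collapse_iin <- function(table) {
  if (!"iin_id" %in% names(table) || all(is.na(table$iin_id))) {
    inform("no iin_id present; collapse_iin is an identity transform")
    return(table)
  }
  area_cols <- setdiff(names(table), FEATURE_CORE_COLS)
  grouped <- table[!is.na(table$iin_id), , drop = FALSE]
  single <- table[is.na(table$iin_id), , drop = FALSE]
  collapse_one <- function(df) {
    totals <- rowSums(as.matrix(df[area_cols]))
    rep_idx <- order(-totals, df$feature_id)[1]
    out <- df[rep_idx, , drop = FALSE]
    out[area_cols] <- as.list(apply(as.matrix(df[area_cols]), 2, max))
    out
  }
  collapsed <- grouped |>
    dplyr::group_split(.data$iin_id) |>
    purrr::map(collapse_one) |>
    bind_rows()
  out <- bind_rows(collapsed, single)
  arrange(out, .data$feature_id)
}

#' Read MS2 spectra from an MGF file
#'
#' Minimal Mascot Generic Format reader: each `BEGIN IONS`/`END IONS` block
#' must carry a `PEPMASS` line; `SCANS` (or `FEATURE_ID`) links the spectrum
#' to a feature id.
#'
#' @param path path to the MGF file.
#' @return a tibble with one row per spectrum: `scan` (integer), `precursor_mz`
#'   and `peaks`, a list-column of tibbles with columns `mz` and `intensity`.
#' @export
read_mgf <- function(path) {
  if (!file.exists(path)) format_error(paste0("MGF not found: ", path))
  lines <- readLines(path, warn = FALSE)
  starts <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(starts) != length(ends)) format_error("unbalanced BEGIN IONS/END IONS")
  if (length(starts) == 0) {
    return(tibble(scan = integer(), precursor_mz = double(), peaks = list()))
  }
  parse_block <- function(i) {
    block <- lines[(starts[i] + 1):(ends[i] - 1)]
    kv <- grepl("=", block, fixed = TRUE)
    keys <- sub("=.*", "", block[kv])
    vals <- sub("^[^=]*=", "", block[kv])
    if (!"PEPMASS" %in% keys) {
      format_error(paste0("MGF block ", i, " lacks PEPMASS"))
    }
    pep <- as.numeric(strsplit(vals[keys == "PEPMASS"][1], "\\s+")[[1]][1])
    scan <- if ("SCANS" %in% keys) as.integer(vals[keys == "SCANS"][1])
            else if ("FEATURE_ID" %in% keys) as.integer(vals[keys == "FEATURE_ID"][1])
            else i
    peak_lines <- block[!kv]
    peak_lines <- peak_lines[nzchar(trimws(peak_lines))]
    if (length(peak_lines)) {
      m <- do.call(rbind, strsplit(trimws(peak_lines), "\\s+"))
      pk <- tibble(mz = as.numeric(m[, 1]), intensity = as.numeric(m[, 2]))
    } else {
      pk <- tibble(mz = double(), intensity = double())
    }
    if (any(pk$intensity < 0) || any(pk$mz <= 0)) {
      validation_error(paste0("MGF block ", i, ": fragment m/z must be > 0 and intensity >= 0"))
    }
    tibble(scan = scan, precursor_mz = pep, peaks = list(pk))
  }
  purrr::map(seq_along(starts), parse_block) |> bind_rows()
}

#' Write MS2 spectra to an MGF file
#'
#' Inverse of [read_mgf()]; used by the fixture generator.
#'
#' @param spectra tibble with columns `scan`, `precursor_mz`, `peaks`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  fmt_block <- function(scan, precursor_mz, pk) {
    c("BEGIN IONS",
      paste0("PEPMASS=", format(precursor_mz, digits = 10)),
      paste0("SCANS=", scan),
      "CHARGE=1+",
      paste(format(pk$mz, digits = 10), format(pk$intensity, digits = 10)),
      "END IONS", "")
  }
  out <- purrr::pmap(
    list(spectra$scan, spectra$precursor_mz, spectra$peaks),
    fmt_block
  )
  writeLines(unlist(out), path)
  invisible(path)
}

#' Write a feature table as an MZmine-style CSV
#'
#' @param table a feature-table tibble.
#' @param path output path.
#' @param mzmine_headers write the long MZmine header dialect (`row ID`,
#'   `" Peak area"` suffixes) instead of plain names.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path, mzmine_headers = FALSE) {
  out <- table
  if (mzmine_headers) {
    area_cols <- setdiff(names(out), FEATURE_CORE_COLS)
    ren <- c("row ID" = "feature_id", "row m/z" = "mz", "row retention time" = "rt")
    if ("iin_id" %in% names(out)) ren <- c(ren, "correlation group ID" = "iin_id")
    if ("adduct" %in% names(out)) ren <- c(ren, "best ion" = "adduct")
    out <- dplyr::rename(out, dplyr::all_of(ren))
    names(out)[match(area_cols, names(out))] <- paste0(area_cols, ".mzML Peak area")
  }
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
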