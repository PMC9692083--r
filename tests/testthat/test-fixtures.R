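# The synthetic-data generator: determinism, planted structure, and
# end-to-end recovery of the ground truth by the full pipeline.

test_that("the same spec and seed give identical bundles", {
  sp <- fixture_spec(n_extracts = 5, n_features = 30, outlier_index = 5, seed = 7)
  b1 <- generate_bundle(sp)
  b2 <- generate_bundle(sp)
  expect_identical(b1$feature_table, b2$feature_table)
  expect_identical(b1$spectra, b2$spectra)
  expect_identical(b1$ground_truth, b2$ground_truth)
  b3 <- generate_bundle(fixture_spec(n_extracts = 5, n_features = 30,
                                     outlier_index = 5, seed = 8))
  expect_false(identical(b1$feature_table, b3$feature_table))
})

test_that("planted structure holds by construction", {
  sp <- fixture_spec(n_extracts = 10, n_features = 100,
                     fraction_specific = 0.6, seed = 7)
  b <- generate_bundle(sp)
  md <- b$metadata
  norm <- normalize_rowwise(b$feature_table, md)
  m <- as.matrix(norm[md$filename[md$sample_type == "sample"]])
  # 60 features concentrate fully in extract 1; extract 1 detects 100
  expect_equal(sum(m[, 1] >= 0.9), 60)
  tbl <- as.matrix(b$feature_table[md$filename[md$sample_type == "sample"]])
  expect_equal(colSums(tbl > 0), rep(100, 10), ignore_attr = TRUE)
  expect_equal(b$ground_truth$FC[1], 0.6)
  # no shared feature reaches the specificity threshold anywhere
  shared <- is.na(rowSums(m)) | rowSums(m > 0) > 1
  expect_true(all(m[shared, ] < 0.9))
})

test_that("infeasible specs and invalid fractions are rejected", {
  expect_error(fixture_spec(n_extracts = 1), class = "npscout_validation_error")
  expect_error(fixture_spec(fraction_specific = 1.2),
               class = "npscout_parameter_error")
})

test_that("skipped-spectrum floor and IIN extras leave ground truth unchanged", {
  sp <- fixture_spec(n_extracts = 4, n_features = 40, fraction_specific = 0.5,
                     outlier_index = 4, n_small_spectra = 3, n_iin_extra = 6,
                     seed = 5)
  b <- generate_bundle(sp)
  # small spectra contribute no words: vectorizing only the full-size spectra
  # gives the same matrix
  memo_all <- memo_vectorize(b$spectra)
  full_only <- b$spectra[vapply(b$spectra$peaks, nrow, 0L) >= 10, ]
  memo_full <- memo_vectorize(full_only)
  expect_equal(as.data.frame(memo_all), as.data.frame(memo_full))
  # IIN collapse restores the planted per-extract detection counts
  collapsed <- collapse_iin(b$feature_table)
  cols <- b$metadata$filename[b$metadata$sample_type == "sample"]
  expect_equal(colSums(as.matrix(collapsed[cols]) > 0),
               rep(40, 4), ignore_attr = TRUE)
})

test_that("the full pipeline recovers the planted ground truth exactly", {
  sp <- fixture_spec(n_extracts = 8, n_features = 50, fraction_specific = 0.4,
                     fraction_annotated = 0.5,
                     plant_new_class = c(TRUE, TRUE, FALSE, TRUE, FALSE,
                                         TRUE, TRUE, TRUE),
                     outlier_index = 3, n_iin_extra = 4, seed = 31)
  b <- generate_bundle(sp)
  res <- suppressMessages(prioritize_extracts(
    b$feature_table, b$metadata, gnps = b$gnps, isdb = b$isdb,
    sirius = b$sirius, predictions = b$predictions,
    occurrence = b$occurrence, spectra = b$spectra
  ))
  got <- dplyr::arrange(res$results, filename)
  truth <- dplyr::arrange(b$ground_truth, filename)
  expect_equal(got$FS, truth$FS)
  expect_equal(got$FC, truth$FC)
  expect_equal(got$CC, truth$CC)
  expect_equal(got$SC, truth$SC)
  expect_equal(got$rcs, truth$rcs)
  expect_equal(got$rcg, truth$rcg)
  expect_equal(got$LC, truth$LC, tolerance = 1e-12)
})

test_that("a written bundle reloads into the same tables", {
  b <- generate_bundle(fixture_spec(n_extracts = 3, n_features = 20,
                                    fraction_annotated = 0.5, seed = 13))
  dir <- withr::local_tempdir()
  write_bundle(b, dir)
  md <- read_extract_metadata(file.path(dir, "metadata.tsv"))
  expect_equal(as.data.frame(md), as.data.frame(b$metadata))
  ft <- read_feature_table(file.path(dir, "feature_table.csv"), metadata = md)
  num_cols <- c("mz", "rt", md$filename)
  expect_equal(as.data.frame(ft[num_cols]),
               as.data.frame(b$feature_table[num_cols]), tolerance = 1e-9)
  gnps <- read_gnps_annotations(file.path(dir, "gnps_annotations.tsv"))
  expect_equal(as.data.frame(gnps), as.data.frame(b$gnps))
  occ <- read_occurrence_table(file.path(dir, "occurrences.tsv"))
  expect_equal(occ$compound_count, b$occurrence$compound_count)
  mgf <- read_mgf(file.path(dir, "spectra", "extract_01.mgf"))
  orig <- dplyr::filter(b$spectra, filename == "extract_01")
  expect_equal(nrow(mgf), nrow(orig))
  expect_equal(mgf$peaks[[1]]$mz, orig$peaks[[1]]$mz, tolerance = 1e-9)
})
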