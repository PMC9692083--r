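# Row-wise normalization, specificity (including shared specificity),
# FS/FC ratios and the two intensity filters.

test_that("row-wise normalization yields proportions and preserves zero rows", {
  tbl <- make_table(rbind(c(2, 3, 5), c(0, 0, 0), c(7, 0, 0)), c("a", "b", "c"))
  md <- make_metadata(c("a", "b", "c"))
  norm <- normalize_rowwise(tbl, md)
  expect_equal(unlist(norm[1, c("a", "b", "c")]), c(a = 0.2, b = 0.3, c = 0.5))
  expect_equal(unlist(norm[2, c("a", "b", "c")]), c(a = 0, b = 0, c = 0))
  expect_equal(norm$a[3], 1)

  single <- make_table(matrix(7, 1, 1, dimnames = list(NULL, "only")))
  expect_equal(normalize_rowwise(single, make_metadata("only"))$only, 1)

  rt <- random_table(17, n_features = 100, n_extracts = 6)
  sums <- rowSums(as.matrix(
    normalize_rowwise(rt$table, rt$metadata)[rt$metadata$filename]
  ))
  expect_true(all(abs(sums - 1) < 1e-9 | sums == 0))
})

test_that("specificity with N = 1 thresholds the normalized share per extract", {
  areas <- rbind(c(92, 5, 3), c(25, 25, 50))
  tbl <- make_table(areas, c("a", "b", "c"))
  md <- make_metadata(c("a", "b", "c"))
  norm <- normalize_rowwise(tbl, md)
  spec <- compute_specificity(norm, md, min_specificity = 0.90, max_occurrence = 1)
  wide <- tidyr::pivot_wider(spec, names_from = "filename", values_from = "specific")
  expect_equal(unlist(wide[1, c("a", "b", "c")]),
               c(a = TRUE, b = FALSE, c = FALSE))
  expect_false(any(unlist(wide[2, c("a", "b", "c")])))
  expect_error(compute_specificity(norm, md, min_specificity = 1.5),
               class = "npscout_parameter_error")
})

test_that("shared specificity pools the top-N extracts of one species", {
  # two extracts of one species holding 0.50 and 0.45 of the feature
  areas <- rbind(c(50, 45, 5))
  tbl <- make_table(areas, c("a1", "a2", "b"))
  md <- make_metadata(c("a1", "a2", "b"), species = c("sp A", "sp A", "sp B"))
  norm <- normalize_rowwise(tbl, md)

  n1 <- compute_specificity(norm, md, 0.90, max_occurrence = 1)
  expect_false(any(n1$specific))
  n2 <- compute_specificity(norm, md, 0.90, max_occurrence = 2)
  wide <- tidyr::pivot_wider(n2, names_from = "filename", values_from = "specific")
  expect_equal(unlist(wide[1, c("a1", "a2", "b")]),
               c(a1 = TRUE, a2 = TRUE, b = FALSE))  # 0.95 >= 0.90, shared
})

test_that("shared specificity matches a brute-force oracle on random tables", {
  # oracle: feature specific to e iff e is among the species' top-k nonzero
  # extracts by share and those top-k shares sum to >= the threshold
  brute <- function(norm_m, species, N, thr) {
    out <- matrix(FALSE, nrow(norm_m), ncol(norm_m))
    for (f in seq_len(nrow(norm_m))) {
      for (sp in unique(species)) {
        idx <- which(species == sp)
        k <- min(N, length(idx))
        ord <- idx[order(-norm_m[f, idx], seq_along(idx))][seq_len(k)]
        ord <- ord[norm_m[f, ord] > 0]
        if (length(ord) && sum(norm_m[f, ord]) >= thr) out[f, ord] <- TRUE
      }
    }
    out
  }
  for (seed in c(3, 14, 27)) {
    rt <- random_table(seed, n_features = 60, n_extracts = 6)
    md <- rt$metadata
    md$species <- rep(c("spA", "spB", "spC"), each = 2)  # 3 species x 2 organs
    norm <- normalize_rowwise(rt$table, md)
    m <- as.matrix(norm[md$filename])
    for (N in c(2, 3)) {
      got <- compute_specificity(norm, md, 0.90, N) |>
        tidyr::pivot_wider(names_from = "filename", values_from = "specific")
      expect_equal(unname(as.matrix(got[md$filename])),
                   brute(m, md$species, N, 0.90))
    }
  }
})

test_that("FS and FC are ratios over detected features, with 0/0 = 0", {
  # 100 detected in extract a: 60 specific unannotated, 10 specific annotated
  areas <- cbind(a = c(rep(100, 70), rep(10, 30)), b = c(rep(0, 70), rep(90, 30)))
  tbl <- make_table(areas)
  md <- make_metadata(c("a", "b"))
  norm <- normalize_rowwise(tbl, md)
  spec <- compute_specificity(norm, md, 0.90, 1)
  ledger <- make_ledger(tbl$feature_id, annotated_ids = 61:70)
  res <- compute_fs_fc(spec, ledger, tbl, md)
  a <- res[res$filename == "a", ]
  expect_equal(a$n_detected, 100)
  expect_equal(a$FC, 0.6)
  expect_equal(a$FS, 0.7)

  all_annot <- make_ledger(tbl$feature_id, annotated_ids = tbl$feature_id)
  expect_equal(compute_fs_fc(spec, all_annot, tbl, md)$FC, c(0, 0))

  empty <- make_table(cbind(a = c(0, 0), b = c(5, 5)))
  norm_e <- normalize_rowwise(empty, md)
  spec_e <- compute_specificity(norm_e, md, 0.90, 1)
  res_e <- compute_fs_fc(spec_e, make_ledger(empty$feature_id), empty, md)
  expect_equal(res_e$FS[res_e$filename == "a"], 0)  # 0/0 defined as 0
})

test_that("FS/FC equal brute-force counting on a seeded 300-feature table", {
  rt <- random_table(8, n_features = 300, n_extracts = 8, sparsity = 0.4)
  md <- rt$metadata
  norm <- normalize_rowwise(rt$table, md)
  spec <- compute_specificity(norm, md, 0.90, 1)
  annotated_ids <- withr::with_seed(8, sample(300, 120))
  ledger <- make_ledger(rt$table$feature_id, annotated_ids)
  res <- compute_fs_fc(spec, ledger, rt$table, md)
  m <- as.matrix(rt$table[md$filename])
  nm <- as.matrix(norm[md$filename])
  for (j in seq_along(md$filename)) {
    det <- which(m[, j] > 0)
    sp <- which(nm[, j] >= 0.90)
    fs <- length(intersect(det, sp)) / length(det)
    fc <- length(setdiff(intersect(det, sp), annotated_ids)) / length(det)
    row <- res[res$filename == md$filename[j], ]
    expect_equal(row$FS, fs)
    expect_equal(row$FC, fc)
    expect_lte(row$FC, row$FS)
  }
})

test_that("monotonicity: stricter specificity lowers FS/FC; larger N never lowers FS", {
  rt <- random_table(23, n_features = 80, n_extracts = 6, sparsity = 0.2)
  md <- rt$metadata
  md$species <- rep(c("spA", "spB"), each = 3)
  norm <- normalize_rowwise(rt$table, md)
  ledger <- make_ledger(rt$table$feature_id, withr::with_seed(23, sample(80, 20)))
  fs_at <- function(thr, N) {
    compute_fs_fc(compute_specificity(norm, md, thr, N), ledger, rt$table, md)
  }
  loose <- fs_at(0.7, 1); strict <- fs_at(0.95, 1)
  expect_true(all(strict$FS <= loose$FS + 1e-12))
  expect_true(all(strict$FC <= loose$FC + 1e-12))
  n1 <- fs_at(0.9, 1); n2 <- fs_at(0.9, 2); n3 <- fs_at(0.9, 3)
  expect_true(all(n2$FS >= n1$FS - 1e-12))
  expect_true(all(n3$FS >= n2$FS - 1e-12))
})

test_that("intensity filter zeroes areas below the per-extract 2% cut", {
  tbl <- make_table(cbind(a = c(100, 1, 50), b = c(10, 5, 0)))
  out <- apply_intensity_filter(tbl, 0.02)
  expect_equal(out$a, c(100, 0, 50))  # 1/100 = 1% < 2%
  expect_equal(out$b, c(10, 5, 0))    # 5/10 = 50% survives
  expect_identical(apply_intensity_filter(tbl, 0), tbl)
  expect_error(apply_intensity_filter(tbl, 1), class = "npscout_parameter_error")
})

test_that("quantile filter keeps values at or above the nonzero q-quantile", {
  tbl <- make_table(cbind(a = c(1, 2, 3, 4), b = c(5, 0, 0, 5)))
  out <- apply_quantile_filter(tbl, 0.75)
  # 0.75-quantile of {1,2,3,4} is 3.25 under linear interpolation
  expect_equal(out$a, c(0, 0, 0, 4))
  expect_equal(out$b, c(5, 0, 0, 5))
  expect_identical(apply_quantile_filter(tbl, 0), tbl)
})

test_that("filters only zero values, never alter survivors, and compose monotonely", {
  rt <- random_table(44, n_features = 120, n_extracts = 5, sparsity = 0.35)
  tbl <- rt$table
  cols <- rt$metadata$filename
  nonzero_count <- function(x) sum(as.matrix(x[cols]) > 0)
  f1 <- apply_intensity_filter(tbl, 0.02)
  f2 <- apply_quantile_filter(tbl, 0.75)
  both <- apply_quantile_filter(f1, 0.75)
  for (f in list(f1, f2, both)) {
    m0 <- as.matrix(tbl[cols]); m1 <- as.matrix(f[cols])
    expect_true(all(m1 == m0 | m1 == 0))          # zero-only
    expect_lte(nonzero_count(f), nonzero_count(tbl))
  }
  expect_lte(nonzero_count(both), min(nonzero_count(f1), nonzero_count(f2)))
  # intensity filter is idempotent (the extract maximum always survives)
  expect_identical(apply_intensity_filter(f1, 0.02), f1)
  # brute-force re-check of the 2% rule
  m0 <- as.matrix(tbl[cols]); m1 <- as.matrix(f1[cols])
  for (j in seq_along(cols)) {
    expect_equal(m1[, j] > 0, m0[, j] > 0 & m0[, j] / max(m0[, j]) >= 0.02)
  }
})
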