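# MS2 word vectorization, blank-word removal and the dissimilarity matrix.

one_spectrum <- function(filename, precursor, mz, intensity = NULL) {
  tibble::tibble(
    scan = 1L, filename = filename, precursor_mz = precursor,
    peaks = list(tibble::tibble(
      mz = mz, intensity = intensity %||% rep(100, length(mz))
    ))
  )
}

test_that("words are binned fragments plus in-window neutral losses", {
  sp <- one_spectrum("e1", 500.00, c(100.004, 480.006, 495.0))
  # wide loss window: peaks round half-away-from-zero to two decimals;
  # 500 - 495 = 5 is below the 10 Da loss floor and emits no loss word;
  # 500 - 100.004 = 399.996 -> 400.00; 500 - 480.006 = 19.994 -> 19.99
  memo <- memo_vectorize(sp, params = memo_params(min_peaks_required = 3,
                                                  losses_to = 500))
  words <- setdiff(names(memo), "filename")
  expect_setequal(words, c("peak@100.00", "peak@480.01", "peak@495.00",
                           "loss@400.00", "loss@19.99"))
  expect_true(all(memo[1, words] == 1))
  # with the default 200 Da ceiling the 399.996 Da loss is out of window
  memo2 <- memo_vectorize(sp, params = memo_params(min_peaks_required = 3))
  expect_false("loss@400.00" %in% names(memo2))
  expect_true("loss@19.99" %in% names(memo2))
})

test_that("spectra below the retained-peak floor contribute no words", {
  sp <- one_spectrum("e1", 500, seq(100, 170, by = 10))  # 8 peaks, floor is 10
  memo <- memo_vectorize(sp)
  expect_equal(setdiff(names(memo), "filename"), character())

  # a peak at 0.5% of the base peak is dropped by the intensity window
  sp2 <- one_spectrum("e1", 500, c(seq(100, 190, by = 10), 250),
                      intensity = c(rep(100, 10), 0.5))
  memo2 <- memo_vectorize(sp2)
  expect_false("peak@250.00" %in% names(memo2))
  expect_true("peak@100.00" %in% names(memo2))
})

test_that("word counts are invariant to spectrum and extract order", {
  b <- generate_bundle(fixture_spec(n_extracts = 4, n_features = 10,
                                    n_spectra = 6, seed = 3))
  spectra <- dplyr::filter(b$spectra, filename != "blank_01")
  m1 <- memo_vectorize(spectra)
  shuffled <- withr::with_seed(1, spectra[sample(nrow(spectra)), ])
  m2 <- memo_vectorize(shuffled)
  key <- function(m) dplyr::arrange(m, filename)[, sort(names(m))]
  expect_equal(key(m1), key(m2))
})

test_that("blank-word removal leaves zero blank support and drops blank rows", {
  memo <- tibble::tibble(
    filename = c("s1", "s2", "blank"),
    `peak@100.00` = c(5L, 3L, 0L),
    `peak@200.00` = c(2L, 0L, 4L),
    `loss@50.00` = c(0L, 1L, 1L)
  )
  out <- remove_blank_words(memo, "blank")
  expect_equal(out$filename, c("s1", "s2"))
  expect_equal(setdiff(names(out), "filename"), "peak@100.00")
  expect_identical(remove_blank_words(memo, character()), memo)

  withr::with_seed(40, {
    big <- tibble::as_tibble(matrix(rpois(8 * 30, 1), 8, 30,
                                    dimnames = list(NULL, sprintf("peak@%d.00", 1:30))))
    big <- dplyr::bind_cols(tibble::tibble(filename = sprintf("x%d", 1:8)), big)
  })
  cleaned <- remove_blank_words(big, c("x7", "x8"))
  blank_words <- names(big)[-1][colSums(big[7:8, -1]) > 0]
  expect_setequal(setdiff(names(big)[-1], blank_words),
                  setdiff(names(cleaned), "filename"))
})

test_that("Bray-Curtis dissimilarity behaves as the count-data metric", {
  memo <- tibble::tibble(
    filename = c("a", "b", "c"),
    w1 = c(3L, 3L, 0L), w2 = c(1L, 1L, 0L), w3 = c(0L, 0L, 7L)
  )
  d <- memo_distance(memo)
  expect_equal(d["a", "b"], 0)     # identical rows
  expect_equal(d["a", "c"], 1)     # disjoint word support
  expect_true(isSymmetric(d))
  expect_equal(diag(d), c(a = 0, b = 0, c = 0))

  withr::with_seed(12, {
    counts <- matrix(rpois(5 * 12, 3), 5, 12)
  })
  memo5 <- dplyr::bind_cols(
    tibble::tibble(filename = sprintf("e%d", 1:5)),
    tibble::as_tibble(matrix(as.integer(counts), 5, 12,
                             dimnames = list(NULL, sprintf("peak@%d.00", 1:12))))
  )
  d5 <- memo_distance(memo5)
  for (i in 1:5) for (j in 1:5) {
    oracle <- sum(abs(counts[i, ] - counts[j, ])) / sum(counts[i, ] + counts[j, ])
    expect_equal(d5[i, j], oracle)
    for (k in 1:5) expect_lte(d5[i, j], d5[i, k] + d5[k, j] + 1e-12)
  }
  expect_error(memo_distance(memo5[1, ]), class = "npscout_validation_error")
})

test_that("word-count matrices round-trip through CSV", {
  b <- generate_bundle(fixture_spec(n_extracts = 3, n_features = 10,
                                    n_spectra = 5, seed = 9))
  memo <- memo_vectorize(b$spectra)
  path <- withr::local_tempfile(fileext = ".csv")
  write_memo_matrix(memo, path)
  expect_equal(as.data.frame(read_memo_matrix(path)), as.data.frame(memo))
})
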