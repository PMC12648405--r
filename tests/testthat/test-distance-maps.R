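make_binned_pairs <- function(distances, arr = NULL) {
  n <- length(distances)
  ids <- paste0("e", seq_len(2 * n))
  df <- data.frame(anode = seq_len(n) * 2 - 1, cathode = seq_len(n) * 2,
                   component_id = "A", distance_mm = distances,
                   ordinal_skip = NA_integer_,
                   anode_id = ids[seq_len(n) * 2 - 1],
                   cathode_id = ids[seq_len(n) * 2])
  bin_pairs_by_distance(bprr:::new_bipolar_pairs(df, "euclidean"),
                        2, c(2, 60))
}

spectra_from_matrix <- function(m, ids = NULL) {
  bprr:::new_spectra(m, 2:(ncol(m) + 1), "linear", 1,
                     ids %||% paste0("s", seq_len(nrow(m))))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("sqrt z-score map normalises each frequency row across bins", {
  pairs <- make_binned_pairs(c(4, 4.5, 8.1, 8.3, 12.5))
  set.seed(1)
  sp <- spectra_from_matrix(matrix(rexp(5 * 10), 5, 10))
  m <- sqrt_zscore_map(sp, pairs, min_pairs = 1)
  filled <- m$n_pairs_per_bin > 0
  for (i in seq_along(m$freq)) {
    row <- m$values[i, filled]
    expect_equal(mean(row), 0, tolerance = 1e-9)
    expect_equal(sqrt(mean(row^2)), 1, tolerance = 1e-9)
  }
  expect_true(all(is.na(m$values[, !filled])))

  # two bins with means 1 and 3 give z-values -1 and +1 (population SD)
  p2 <- make_binned_pairs(c(4, 8.1))
  sp2 <- spectra_from_matrix(rbind(rep(1, 4), rep(9, 4)))  # sqrt -> 1 and 3
  m2 <- sqrt_zscore_map(sp2, p2, min_pairs = 1)
  expect_equal(unname(m2$values[1, m2$n_pairs_per_bin > 0]), c(-1, 1))

  # identical bins give an all-zero row
  sp3 <- spectra_from_matrix(rbind(rep(4, 4), rep(4, 4)))
  m3 <- sqrt_zscore_map(sp3, p2, min_pairs = 1)
  expect_true(all(m3$values[, m3$n_pairs_per_bin > 0] == 0))

  # fewer than 2 populated bins is an error
  p1 <- make_binned_pairs(4)
  expect_error(sqrt_zscore_map(spectra_from_matrix(matrix(1, 1, 4)), p1,
                               min_pairs = 1), "invalid map")
})

test_that("percent change hits the analytic poles at -100% and +100%", {
  # pure common-mode input: bipolar identically zero -> -100% everywhere
  pairs <- make_binned_pairs(c(4, 20))
  bip <- spectra_from_matrix(matrix(0, 2, 6))
  ref <- spectra_from_matrix(matrix(5, 4, 6), paste0("e", 1:4))
  m <- percent_change_map(bip, ref, pairs, min_pairs = 1)
  expect_true(all(m$values[, m$n_pairs_per_bin > 0] == -100))

  # independent equal-power noise doubles variance -> +100%
  arr <- line_array(2, 40)
  prs <- bin_pairs_by_distance(enumerate_omnidirectional_pairs(arr))
  w <- noise_windows(2, 300, 512, seed = 12)
  w$channel_ids <- arr$contact_id
  bip2 <- bipolar_psd(w, prs)
  ref2 <- multitaper_psd(w)
  m2 <- percent_change_map(bip2, ref2, prs, min_pairs = 1)
  pc <- mean(m2$values[, m2$n_pairs_per_bin > 0])
  expect_equal(pc, 100, tolerance = 5)

  # legacy sign convention flips the direction
  m3 <- percent_change_map(bip2, ref2, prs, min_pairs = 1, legacy_sign = TRUE)
  expect_lt(mean(m3$values[, m3$n_pairs_per_bin > 0]), 0)
})

test_that("empty bins are NA (never zero) and min_pairs is honoured", {
  pairs <- make_binned_pairs(c(4, 4.2, 4.4, 20))
  set.seed(2)
  sp <- spectra_from_matrix(matrix(rexp(4 * 5) + 1, 4, 5))
  ref <- spectra_from_matrix(matrix(1, 8, 5), paste0("e", 1:8))
  m <- percent_change_map(sp, ref, pairs, min_pairs = 3)
  b20 <- which(m$bin_centers_mm == 21)
  expect_equal(m$n_pairs_per_bin[b20], 1L)
  expect_true(all(is.na(m$values[, b20])))   # below min_pairs
  b4 <- which(m$bin_centers_mm == 5)
  expect_false(any(is.na(m$values[, b4])))
})

test_that("subject-level band tests match the signed-rank oracle and flag nothing under the null", {
  freq <- 2:21
  mk_subject <- function(offset) {
    ref <- bprr:::new_spectra(matrix(2, 3, length(freq)), freq, "linear", 1,
                              paste0("e", 1:3))
    bip <- bprr:::new_spectra(matrix(2 + offset, 4, length(freq)), freq,
                              "linear", 1, paste0("b", 1:4))
    list(referential = ref, bipolar = list("4" = bip))
  }
  null_data <- lapply(rep(0, 6), mk_subject)
  res0 <- band_summary_tests(null_data, bands = band_table()[1:2, ])
  expect_true(all(res0$effect_size == 0))
  expect_false(any(res0$significant))

  # known offsets: paired differences {1,2,3,4,5,-1}
  offs <- c(1, 2, 3, 4, 5, -0.5)   # tie-free so the exact test applies
  data1 <- lapply(offs, mk_subject)
  res1 <- band_summary_tests(data1, bands = band_table()[1, , drop = FALSE])
  expect_equal(res1$p[1], brute_force_signed_rank_p(offs), tolerance = 1e-12)
  expect_equal(res1$median_diff[1], median(offs))

  # single subject: descriptives only
  res2 <- band_summary_tests(data1[1], bands = band_table()[1, , drop = FALSE])
  expect_true(is.na(res2$p))
  expect_false(is.na(res2$median_diff))
})

test_that("equal-weight averaging of per-subject maps keeps NA bookkeeping", {
  pairs <- make_binned_pairs(c(4, 8.1))
  mk <- function(v) {
    sp <- spectra_from_matrix(rbind(rep(v, 3), rep(4 * v, 3)))
    sqrt_zscore_map(sp, pairs, min_pairs = 1)
  }
  avg <- average_distance_maps(list(mk(1), mk(9)))
  expect_equal(dim(avg$values), dim(mk(1)$values))
  filled <- avg$n_pairs_per_bin > 0
  expect_false(any(is.na(avg$values[, filled])))
  expect_true(all(is.na(avg$values[, !filled])))
})
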