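test_that("euclidean distance matches the sum-of-squares oracle", {
  expect_equal(euclidean_distance(c(0, 0, 0), c(3, 4, 0)), 5)
  expect_equal(euclidean_distance(c(1, 1, 1), c(1, 1, 1)), 0)
  set.seed(11)
  for (i in 1:100) {
    a <- runif(3, -50, 50); b <- runif(3, -50, 50)
    oracle <- sqrt((a[1] - b[1])^2 + (a[2] - b[2])^2 + (a[3] - b[3])^2)
    expect_equal(euclidean_distance(a, b), oracle, tolerance = 1e-12)
    expect_equal(euclidean_distance(a, b), euclidean_distance(b, a))
  }
  expect_error(euclidean_distance(c(0, 0, NA), c(1, 1, 1)), "invalid")
})

test_that("linear ordinal pairs follow skip-times-pitch with closed-form counts", {
  row16 <- grid_row_array(16, 4)
  p1 <- enumerate_linear_ordinal_pairs(row16, max_skip = 1)
  expect_equal(nrow(p1), 15)
  expect_true(all(p1$distance_mm == 4))

  depth10 <- line_array(10, 5)
  p2 <- enumerate_linear_ordinal_pairs(depth10, max_skip = 2)
  p2s <- p2[p2$ordinal_skip == 2, ]
  expect_equal(nrow(p2s), 8)
  expect_true(all(p2s$distance_mm == 10))

  expect_equal(nrow(enumerate_linear_ordinal_pairs(line_array(2, 5),
                                                   max_skip = 2)), 1)
  # a 2-contact line has no skip-2 pair at all
  p3 <- enumerate_linear_ordinal_pairs(line_array(2, 5), max_skip = 2)
  expect_equal(sum(p3$ordinal_skip == 2), 0)

  # count identity sum_s (n - s) per line
  for (n in c(4, 7, 10)) {
    p <- enumerate_linear_ordinal_pairs(line_array(n, 3), max_skip = 3)
    expect_equal(nrow(p), sum(n - seq_len(min(3, n - 1))))
  }

  # bad contacts excluded from every enumeration
  arr_bad <- line_array(10, 5, bad = c(rep(FALSE, 4), TRUE, rep(FALSE, 5)))
  pb <- enumerate_linear_ordinal_pairs(arr_bad, max_skip = 1)
  expect_equal(nrow(pb), 7)   # contacts 4-5 and 5-6 missing
  expect_false(any(pb$anode_id == "L05" | pb$cathode_id == "L05"))
})

test_that("omnidirectional pairs stay within components with N(N-1)/2 counts", {
  g <- make_geometry("grid16x16")
  p <- enumerate_omnidirectional_pairs(g)
  expect_equal(nrow(p), 256 * 255 / 2)

  two <- electrode_array(paste0("c", 1:8),
                         cbind(c(0:3, 0:3) * 5, rep(c(0, 30), each = 4), 0),
                         component_id = rep(c("A", "B"), each = 4),
                         component_type = "depth", pitch_mm = 5)
  p2 <- enumerate_omnidirectional_pairs(two)
  expect_equal(nrow(p2), 12)
  a_comp <- two$component_id[p2$anode]
  c_comp <- two$component_id[p2$cathode]
  expect_true(all(a_comp == c_comp))

  mini <- line_array(2, 7)
  p3 <- enumerate_omnidirectional_pairs(mini)
  expect_equal(nrow(p3), 1)
  expect_equal(p3$distance_mm, 7)
})

test_that("distance binning is half-open with out-of-range pairs dropped", {
  arr <- electrode_array(paste0("c", 1:4),
                         rbind(c(0, 0, 0), c(4, 0, 0), c(5.9, 30, 0),
                               c(6, -20, 0)),
                         "A", "depth", 5)
  df <- data.frame(anode = c(1, 1, 1), cathode = c(2, 3, 4),
                   component_id = "A", distance_mm = c(4, 5.9, 6),
                   ordinal_skip = NA_integer_,
                   anode_id = "c1", cathode_id = c("c2", "c3", "c4"))
  pairs <- bprr:::new_bipolar_pairs(df, "euclidean")
  b <- bin_pairs_by_distance(pairs, 2, c(2, 60))
  expect_equal(b$bin_index, c(1L, 1L, 2L))

  df2 <- df; df2$distance_mm <- c(60.5, 1.9, 30)
  pairs2 <- bprr:::new_bipolar_pairs(df2, "euclidean")
  b2 <- bin_pairs_by_distance(pairs2, 2, c(2, 60))
  expect_equal(nrow(b2), 1)
  expect_equal(b2$distance_mm, 30)

  empty <- bprr:::new_bipolar_pairs(df[0, ], "euclidean")
  expect_equal(nrow(bin_pairs_by_distance(empty)), 0)
  expect_error(bin_pairs_by_distance(pairs, 2, c(60, 2)), "invalid config")
})

test_that("bipolar subtraction cancels common mode and fixes sign by convention", {
  arr <- line_array(3, 4)
  pairs <- enumerate_omnidirectional_pairs(arr)
  tt <- seq(0, 1, length.out = 100)
  rec <- ieeg_recording(rbind(2 * tt, tt, tt), fs = 100, arr$contact_id)
  bip <- apply_bipolar(rec, pairs)
  # anode 2t minus cathode t equals t
  expect_equal(bip$samples[1, ], tt)
  # identical channels give all-zero derivation
  expect_equal(bip$samples[3, ], rep(0, 100))

  # a common-mode component cancels in every bipolar derivation
  rec2 <- ieeg_recording(sweep(rec$samples, 2, sin(2 * pi * 60 * tt), "+"),
                         100, arr$contact_id)
  expect_equal(apply_bipolar(rec2, pairs)$samples, bip$samples,
               tolerance = 1e-12)

  # swapping anode/cathode negates the signal, power unchanged
  swapped <- as.data.frame(pairs)[, ]
  tmp <- swapped$anode; swapped$anode <- swapped$cathode; swapped$cathode <- tmp
  tmp <- swapped$anode_id; swapped$anode_id <- swapped$cathode_id
  swapped$cathode_id <- tmp
  swapped <- bprr:::new_bipolar_pairs(swapped, "euclidean")
  set.seed(2)
  recr <- ieeg_recording(matrix(rnorm(300), 3), 100, arr$contact_id)
  b1 <- apply_bipolar(recr, pairs)$samples
  b2 <- apply_bipolar(recr, swapped)$samples
  expect_equal(b2, -b1)
  expect_equal(rowSums(b2^2), rowSums(b1^2))

  # two unit sinusoids 90 degrees apart: derived variance = 2x single
  fs <- 1000
  t2 <- (0:(10 * fs - 1)) / fs
  rec3 <- ieeg_recording(rbind(sin(2 * pi * 5 * t2),
                               sin(2 * pi * 5 * t2 + pi / 2),
                               0 * t2), fs, arr$contact_id)
  b3 <- apply_bipolar(rec3, pairs)
  expect_equal(var(b3$samples[1, ]) / var(rec3$samples[1, ]), 2,
               tolerance = 1e-3)

  # missing channel is a montage error naming the pair
  expect_error(apply_bipolar(ieeg_recording(matrix(0, 2, 10), 100,
                                            c("L01", "L02")), pairs),
               "montage error")
})

test_that("electrode and pair tables round-trip through TSV", {
  arr <- make_geometry("depth10")
  arr$bad[3] <- TRUE
  f <- tempfile(fileext = ".tsv")
  write_electrode_table(arr, f)
  back <- read_electrode_table(f)
  expect_equal(as.data.frame(back), as.data.frame(arr))

  pairs <- bin_pairs_by_distance(enumerate_omnidirectional_pairs(arr))
  f2 <- tempfile(fileext = ".tsv")
  write_pair_table(pairs, f2)
  tab <- read.delim(f2)
  expect_equal(nrow(tab), nrow(pairs))
  expect_equal(tab$distance_mm, pairs$distance_mm)
  expect_equal(tab$bin_index, pairs$bin_index)
})
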