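test_that("line length matches brute-force absolute-difference sums", {
  expect_true(all(line_length_transform(rep(3.3, 100), 100) == 0))

  ramp <- cumsum(rep(2, 50))
  ll <- line_length_transform(ramp, 100)
  expect_true(all(ll[2:50] == 2))

  fs <- 512
  x <- sin(2 * pi * 10 * (0:(fs - 1)) / fs)
  llw <- line_length_transform(x, fs, window_ms = 100)
  wlen <- round(0.1 * fs)
  d <- c(abs(diff(x))[1], abs(diff(x)))
  half_l <- floor((wlen - 1) / 2); half_r <- wlen - 1 - half_l
  brute <- sapply(seq_len(fs), function(t)
    sum(d[max(1, t - half_l):min(fs, t + half_r)]))
  expect_equal(unname(llw), brute)
  expect_true(any(attr(line_length_transform(matrix(x, 1), fs, 100),
                       "partial_edge")))

  # invariance to offset, linear in amplitude
  expect_equal(line_length_transform(x + 50, fs), line_length_transform(x, fs))
  expect_equal(line_length_transform(3 * x, fs),
               3 * line_length_transform(x, fs))
  expect_error(line_length_transform(x[1:10], fs, window_ms = 100), "longer")
})

test_that("density schemes share base electrodes with 4 vs 8 mm (or 5 vs 10 mm) pairs", {
  row16 <- grid_row_array(16, 4)
  sch <- build_density_schemes(row16)
  expect_equal(nrow(sch$high), 8)
  expect_equal(nrow(sch$low), 7)     # base 15 has no +2 partner
  expect_true(all(sch$high$distance_mm == 4))
  expect_true(all(sch$low$distance_mm == 8))
  expect_setequal(intersect(sch$high$anode_id, sch$low$anode_id),
                  sch$low$anode_id)
  # base electrodes are every other contact
  expect_equal(sch$high$anode_id,
               sprintf("G%02d", seq(1, 15, by = 2)))

  depth <- make_geometry("depth10")
  schd <- build_density_schemes(depth)
  expect_true(all(schd$high$distance_mm == 5))
  expect_true(all(schd$low$distance_mm == 10))

  tri <- line_array(3, 4)
  scht <- build_density_schemes(tri)
  expect_equal(nrow(scht$high), 1)
  expect_equal(nrow(scht$low), 1)
  expect_equal(scht$high$anode_id, scht$low$anode_id)
})

test_that("the IED inclusion rule separates 49 from 51 windows", {
  expect_message(ok49 <- ied_inclusion(49), "skipped")
  expect_false(ok49)
  expect_silent(ok51 <- ied_inclusion(51))
  expect_true(ok51)
})

test_that("duplicated baseline windows yield no significant channels", {
  w <- noise_windows(4, 24, 256, seed = 21)
  ied_w <- w; ied_w$info$label <- "ied"
  res <- ied_channel_cluster_test(ied_w, w, n_perm = 200, seed = 3,
                                  match_baseline = FALSE)
  expect_false(any(res$channels$significant))
  expect_equal(sum(res$sig_masks), 0)
  expect_error(ied_channel_cluster_test(ied_w, w, n_perm = 50), "invalid config")
})

test_that("extent metrics convert significant samples to milliseconds", {
  w <- noise_windows(2, 24, 512, seed = 22)
  ied_w <- w; ied_w$info$label <- "ied"
  res <- ied_channel_cluster_test(ied_w, w, n_perm = 150, seed = 4,
                                  match_baseline = FALSE)
  ext0 <- ied_extent_metrics(res)
  expect_equal(ext0$n_significant_channels, 0)
  expect_equal(ext0$mean_width_ms, 0)

  # synthetic result: one channel with 51 significant samples at 512 Hz
  res$channels$significant <- c(TRUE, FALSE)
  res$channels$sig_samples <- c(51L, 0L)
  ext <- ied_extent_metrics(res, "high")
  expect_equal(ext$n_significant_channels, 1)
  expect_equal(ext$mean_width_ms, 51 * 1000 / 512, tolerance = 1e-9)
  expect_equal(unname(ext$per_channel_ms[1]), 99.609375)
})

test_that("density comparison uses exact signed-rank p and the Bonferroni threshold", {
  h <- data.frame(mean_width_ms = c(10, 12, 14, 16, 18, 20),
                  n_significant_channels = c(3, 4, 5, 4, 3, 5))
  res_same <- compare_density_conditions(h, h)
  expect_true(all(res_same$p == 1))
  expect_false(any(res_same$significant))
  expect_equal(unique(res_same$threshold), 0.0125)

  l <- h; l$mean_width_ms <- h$mean_width_ms - c(1, 2, 3, 4, 5, 6)
  res <- compare_density_conditions(h, l)
  row <- res[res$metric == "mean_width_ms", ]
  expect_equal(row$p, brute_force_signed_rank_p(c(1, 2, 3, 4, 5, 6)),
               tolerance = 1e-12)
  expect_equal(row$p, 2 / 64)        # all-positive differences, n = 6
  expect_false(row$significant)      # 0.03125 > 0.0125
  expect_equal(row$effect_size, 1)

  expect_equal(unique(compare_density_conditions(h, l, n_conditions = 2,
                                                 family_alpha = 0.1)$threshold),
               0.05)
})

test_that("BH-FDR matches the exhaustive step-up oracle", {
  expect_false(any(bh_fdr(rep(1, 5))$reject))
  p <- c(0.001, 0.008, 0.039, 0.041, 0.17, 0.5)
  res <- bh_fdr(p, 0.05)
  expect_equal(res$reject, brute_force_bh_reject(p, 0.05))
  expect_equal(res$p_adjusted, p.adjust(p, "BH"))
  # adjusted p monotone in raw-p rank
  expect_true(all(diff(res$p_adjusted[order(p)]) >= -1e-12))
  expect_true(bh_fdr(0.04, 0.05)$reject)
  expect_error(bh_fdr(c(0.1, 1.2)), "invalid input")

  set.seed(33)
  for (i in 1:20) {
    p <- runif(sample(3:8, 1))
    expect_equal(bh_fdr(p, 0.05)$reject, brute_force_bh_reject(p, 0.05))
  }
})

test_that("injected discharges are recovered on the right channels", {
  fs <- 256
  set.seed(41)
  nch <- 8
  # scale so the template's peak slope is 8x the baseline mean |first diff|
  tpl0 <- ied_template(fs)
  tpl <- tpl0 * 8 * sqrt(2) * sqrt(2 / pi) / max(abs(diff(tpl0)))
  base <- noise_windows(nch, 25, fs, seed = 42)
  ied <- noise_windows(nch, 25, fs, seed = 43, label = "ied")
  s0 <- fs / 2 - round(length(tpl) / 2)
  for (j in seq_len(25)) {
    for (ch in 3:7) {
      ied$data[ch, s0:(s0 + length(tpl) - 1), j] <-
        ied$data[ch, s0:(s0 + length(tpl) - 1), j] + tpl
    }
  }
  res <- ied_channel_cluster_test(ied, base, n_perm = 200, seed = 5,
                                  match_baseline = FALSE)
  expect_true(all(res$channels$significant[3:7]))
  # significant samples concentrate around the discharge
  sig_cols <- which(colSums(res$sig_masks[3:7, ]) > 0)
  expect_true(mean(sig_cols >= s0 - 25 & sig_cols <= s0 + length(tpl) + 25) >
                0.9)
})
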