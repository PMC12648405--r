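test_that("standard geometries have the manufactured layout", {
  g <- make_geometry("grid16x16")
  expect_equal(nrow(g), 256)
  pos <- cbind(g$x_mm, g$y_mm, g$z_mm)
  nn <- apply(as.matrix(dist(pos)) + diag(Inf, 256), 1, min)
  expect_true(all(nn == 4))
  expect_equal(length(unique(g$row_id)), 16)
  expect_equal(sum(g$row_id == "R01"), 16)

  d <- make_geometry("depth10")
  expect_equal(nrow(d), 10)
  expect_equal(max(dist(cbind(d$x_mm, d$y_mm, d$z_mm))), 45)  # 9 x 5 mm

  j1 <- make_geometry("strip6", jitter_mm = 0.5, seed = 4)
  j2 <- make_geometry("strip6", jitter_mm = 0.5, seed = 4)
  expect_identical(cbind(j1$x_mm, j1$y_mm, j1$z_mm),
                   cbind(j2$x_mm, j2$y_mm, j2$z_mm))
  expect_error(make_geometry("probe128"), "invalid config")
})

test_that("the plane-wave power-ratio oracle has the right landmarks", {
  expect_equal(analytic_pair_power_ratio(0, 48), 0)
  expect_equal(analytic_pair_power_ratio(24, 48), 4)     # d = lambda/2
  expect_equal(analytic_pair_power_ratio(8, 48), 1)      # d = lambda/6
  # oblique pairs see the projected separation
  expect_equal(analytic_pair_power_ratio(16, 48, theta_deg = 60),
               analytic_pair_power_ratio(8, 48))
  # direction-averaged version: small-d limit 2(1 - J0(x)) ~ x^2/2
  x <- 2 * pi * 0.5 / 48
  expect_equal(analytic_bin_power_ratio(0.5, 48), x^2 / 2, tolerance = 1e-3)
  expect_equal(analytic_aperiodic_power_ratio(4, 4), 2 * (1 - exp(-1)))
})

test_that("simulated fields reproduce the closed-form power ratios", {
  # common-mode only: every bipolar derivation is zero
  arr <- line_array(4, 6)
  cm_only <- field_config(aperiodic = list(power = 0, exponent = 1,
                                           coherence_mm = 4, band = c(2, Inf)),
                          common_mode = list(freq_hz = c(60, 85),
                                             amplitude = c(20, 5)))
  rec <- simulate_field(arr, cm_only, 4, fs = 512, seed = 1)
  bip <- apply_bipolar(rec, enumerate_omnidirectional_pairs(arr))
  expect_lt(max(abs(bip$samples)), 1e-9)

  # single wave: colinear pair at 12 mm with lambda = 72 mm -> ratio 1
  arr2 <- electrode_array(c("a", "b"), rbind(c(0, 0, 0), c(12, 0, 0)),
                          "L", "depth", 12)
  wave <- field_config(waves = data.frame(freq_hz = 10, amplitude = 40,
                                          speed_mps = 0.72, bearing_deg = 0,
                                          phase = 0.7),
                       aperiodic = list(power = 0, exponent = 1,
                                        coherence_mm = 4, band = c(2, Inf)))
  rec2 <- simulate_field(arr2, wave, 60, fs = 512, seed = 2)
  r <- empirical_pair_power_ratio(rec2, enumerate_omnidirectional_pairs(arr2))
  expect_equal(r, 1, tolerance = 0.05)

  # aperiodic only, l = 4 mm: ratio 2(1 - e^-1) at 4 mm
  arr3 <- line_array(2, 4)
  ap <- field_config(aperiodic = list(power = 50, exponent = 1,
                                      coherence_mm = 4, band = c(2, Inf)))
  rec3 <- simulate_field(arr3, ap, 60, fs = 512, seed = 3)
  r3 <- empirical_pair_power_ratio(rec3, enumerate_omnidirectional_pairs(arr3))
  expect_equal(r3, 2 * (1 - exp(-1)), tolerance = 0.08)

  # bit-reproducibility
  recA <- simulate_field(arr3, ap, 2, fs = 512, seed = 9)
  recB <- simulate_field(arr3, ap, 2, fs = 512, seed = 9)
  expect_identical(recA$samples, recB$samples)
  expect_error(simulate_field(arr3, ap, 1, fs = 512), "invalid config")
})

test_that("injected discharges have the requested count, footprint and annotations", {
  arr <- make_geometry("depth10", pitch_mm = 4)
  base <- ieeg_recording(matrix(0, 10, 512 * 70), 512, arr$contact_id)
  cfg <- ied_config(20, center_contact = arr$contact_id[5], sigma_mm = 8,
                    amplitude_uv = 100)
  out <- inject_ieds(base, arr, cfg, seed = 6)
  expect_equal(nrow(out$annotations), 20)
  expect_true(all(out$annotations$kind == "ied"))
  # events separated by at least 1 s
  expect_true(all(diff(out$annotations$onset_s) >= 1))
  # annotations bracket the added energy
  for (i in seq_len(5)) {
    s0 <- round(out$annotations$onset_s[i] * 512) + 1
    s1 <- round(out$annotations$offset_s[i] * 512)
    expect_gt(max(abs(out$recording$samples[5, s0:s1])), 50)
  }
  # Gaussian footprint: contact at 16 mm has amplitude e^-2 of the centre
  peak5 <- max(abs(out$recording$samples[5, ]))
  peak9 <- max(abs(out$recording$samples[9, ]))   # 16 mm away
  expect_equal(peak9 / peak5, exp(-2), tolerance = 1e-6)

  none <- inject_ieds(base, arr, ied_config(0, arr$contact_id[5]), seed = 6)
  expect_identical(none$recording$samples, base$samples)
  expect_error(inject_ieds(ieeg_recording(matrix(0, 10, 512 * 3), 512,
                                          arr$contact_id), arr, cfg),
               "invalid config")
})

test_that("task modulation scales band power by the requested gain on subset contacts", {
  arr <- line_array(4, 10)
  ap <- field_config(aperiodic = list(power = 50, exponent = 0,
                                      coherence_mm = 4, band = c(2, Inf)))
  rec <- simulate_field(arr, ap, 20, fs = 512, seed = 11)
  ivs <- rbind(c(2, 6), c(10, 14))
  out <- inject_task_modulation(rec, arr$contact_id[1:2], ivs,
                                gain_band = c(50, 200), gain = 1.5)
  expect_equal(nrow(out$annotations), 2)
  band_power <- function(x, fs) {
    sp <- multitaper_psd(ieeg_windows(array(x, c(1, length(x), 1)), fs))
    mean(sp$power[, sp$freq >= 55 & sp$freq <= 195])
  }
  stim_idx <- c(3 * 512 + 1):(5 * 512)   # inside interval 1, past the ramp
  base_idx <- c(7 * 512 + 1):(9 * 512)
  for (ch in 1:2) {
    r <- band_power(out$recording$samples[ch, stim_idx], 512) /
      band_power(out$recording$samples[ch, base_idx], 512)
    expect_equal(r, 1.5, tolerance = 0.15)
  }
  r3 <- band_power(out$recording$samples[3, stim_idx], 512) /
    band_power(out$recording$samples[3, base_idx], 512)
  expect_equal(r3, 1, tolerance = 0.05)

  same <- inject_task_modulation(rec, arr$contact_id[1:2], ivs, gain = 1)
  expect_identical(same$recording$samples, rec$samples)
  expect_warning(inject_task_modulation(rec, arr$contact_id[1], rbind(c(2, 6), c(5, 8))),
                 "merged")
  expect_error(inject_task_modulation(rec, arr$contact_id[1], rbind(c(18, 25))),
               "invalid config")
})
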