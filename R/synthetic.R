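# Synthetic multi-electrode field generator. The low-frequency field is a
# superposition of traveling plane waves whose spatial wavelength is tied to
# temporal frequency by lambda(f) = v / f; higher frequencies are an
# aperiodic (1/f) field whose inter-electrode coherence decays
# exponentially with distance; a common-mode component (mains harmonics and
# narrow >75 Hz reference-contact peaks) is identical on every contact.
# Closed-form oracles link bipolar distance to power ratios for each part.

#' Build a standard electrode geometry
#'
#' Planar grid lattices and colinear depth/strip lines with the study's
#' manufactured pitches. `row_id` is populated for grids (contacts ordered
#' within each row).
#'
#' @param kind one of `"grid16x16"`, `"grid12x12"`, `"grid8x8"`,
#'   `"depth10"`, `"strip4"`, `"strip6"`.
#' @param pitch_mm inter-contact spacing in mm (defaults: 4 for grids, 5
#'   for depths, 10 for strips).
#' @param jitter_mm SD of optional Gaussian coordinate jitter (default 0).
#' @param seed RNG seed for the jitter.
#' @return An [electrode_array()].
#' @export
make_geometry <- function(kind = c("grid16x16", "grid12x12", "grid8x8",
                                   "depth10", "strip4", "strip6"),
                          pitch_mm = NULL, jitter_mm = 0, seed = 1L) {
  kind <- tryCatch(match.arg(kind),
                   error = function(e) stop("invalid config: unknown geometry kind",
                                            call. = FALSE))
  spec <- switch(kind,
    grid16x16 = list(type = "grid", nr = 16L, nc = 16L, pitch = 4),
    grid12x12 = list(type = "grid", nr = 12L, nc = 12L, pitch = 4),
    grid8x8   = list(type = "grid", nr = 8L,  nc = 8L,  pitch = 4),
    depth10   = list(type = "depth", n = 10L, pitch = 5),
    strip4    = list(type = "strip", n = 4L,  pitch = 10),
    strip6    = list(type = "strip", n = 6L,  pitch = 10))
  pitch <- if (is.null(pitch_mm)) spec$pitch else pitch_mm
  if (pitch <= 0) stop("invalid config: pitch must be > 0", call. = FALSE)
  if (spec$type == "grid") {
    g <- expand.grid(col = seq_len(spec$nc), row = seq_len(spec$nr))
    pos <- cbind((g$col - 1) * pitch, (g$row - 1) * pitch, 0)
    ids <- sprintf("G%03d", seq_len(nrow(g)))
    row_id <- sprintf("R%02d", g$row)
  } else {
    n <- spec$n
    pos <- cbind((seq_len(n) - 1) * pitch, 0, 0)
    ids <- sprintf("%s%02d", toupper(substr(spec$type, 1, 1)), seq_len(n))
    row_id <- NA_character_
  }
  if (jitter_mm > 0) {
    pos <- pos + with_local_seed(seed,
      matrix(stats::rnorm(length(pos), 0, jitter_mm), nrow(pos)))
  }
  electrode_array(ids, pos, component_id = kind,
                  component_type = spec$type, pitch_mm = pitch,
                  row_id = row_id)
}

#' Field configuration for the synthetic generator
#'
#' @param waves data frame with columns `freq_hz`, `amplitude` (uV),
#'   `speed_mps` (propagation speed; spatial wavelength is
#'   `1000 * speed_mps / freq_hz` mm), `bearing_deg` (propagation direction
#'   in the array plane), `phase` (radians).
#' @param aperiodic list: `power` (density scale K, giving K/f^`exponent`
#'   uV^2/Hz), `exponent`, `coherence_mm` (exponential spatial coherence
#'   length), `band` (frequency support, Hz).
#' @param common_mode list: `freq_hz`, `amplitude` for tones added
#'   identically to every contact (mains harmonics, >75 Hz reference
#'   artifact peaks).
#' @return List of class `field_config`.
#' @export
field_config <- function(waves = NULL,
                         aperiodic = list(power = 100, exponent = 1,
                                          coherence_mm = 4, band = c(2, Inf)),
                         common_mode = list(freq_hz = numeric(),
                                            amplitude = numeric())) {
  if (is.null(waves)) {
    waves <- data.frame(freq_hz = numeric(), amplitude = numeric(),
                        speed_mps = numeric(), bearing_deg = numeric(),
                        phase = numeric())
  }
  stopifnot(all(c("freq_hz", "amplitude", "speed_mps", "bearing_deg",
                  "phase") %in% names(waves)),
            all(waves$amplitude >= 0), all(waves$freq_hz > 0),
            all(waves$speed_mps > 0),
            aperiodic$coherence_mm > 0, aperiodic$power >= 0)
  structure(list(waves = waves, aperiodic = aperiodic,
                 common_mode = common_mode),
            class = "field_config")
}

#' Reference field configuration
#'
#' The default study conditions: a traveling-wave continuum over 2-30 Hz
#' (components every 0.5 Hz, spatial wavelength `lambda(f) = v/f` with
#' `v = 0.72 m/s`, random bearing and phase per component) carrying about
#' 40% of the low-frequency power, discrete wave peaks at 4, 8, 12, 20 and
#' 28 Hz, a broadband 1/f aperiodic field with 4 mm spatial coherence
#' length covering the full analysis band, and common-mode line noise
#' (60/120/180/240 Hz) plus two low-amplitude narrowband reference-artifact
#' peaks above 75 Hz (85 and 105 Hz). Amplitudes are in microvolts.
#'
#' @param speed_mps wave propagation speed (default 0.72).
#' @param aperiodic_power density scale K of the aperiodic field (K/f
#'   uV^2/Hz; default 100).
#' @param coherence_mm aperiodic spatial coherence length (default 4).
#' @param peak_freqs discrete wave-peak frequencies (Hz).
#' @param seed seed for the per-component bearings and phases.
#' @return A [field_config()].
#' @export
reference_field_config <- function(speed_mps = 0.72, aperiodic_power = 100,
                                   coherence_mm = 4,
                                   peak_freqs = c(4, 8, 12, 20, 28),
                                   seed = 7L) {
  K <- aperiodic_power
  f_cont <- seq(2, 30, by = 0.5)
  # continuum density (2/3)K/f over a 0.5 Hz slot -> amplitude sqrt(2*dens*df)
  a_cont <- sqrt(2 * (2 / 3) * K / f_cont * 0.5)
  a_peak <- sqrt(0.6 * K / peak_freqs)   # peak power 0.3*K/f on top
  f_all <- c(f_cont, peak_freqs)
  a_all <- c(a_cont, a_peak)
  rnd <- with_local_seed(seed, list(bearing = stats::runif(length(f_all), 0, 360),
                                    phase = stats::runif(length(f_all), 0, 2 * pi)))
  field_config(
    waves = data.frame(freq_hz = f_all, amplitude = a_all,
                       speed_mps = speed_mps, bearing_deg = rnd$bearing,
                       phase = rnd$phase),
    aperiodic = list(power = K, exponent = 1, coherence_mm = coherence_mm,
                     band = c(2, Inf)),
    common_mode = list(freq_hz = c(60, 120, 180, 240, 85, 105),
                       amplitude = c(20, 10, 6, 4, 1, 1)))
}

#' Simulate a referential multi-electrode recording
#'
#' Each contact at position `r` receives (i) every wave component as
#' `A cos(2 pi f t - (2 pi / lambda) u.r + phi)` with `lambda = 1000 v / f`
#' mm and `u` the in-plane propagation direction, (ii) an aperiodic field
#' with per-frequency density `K / f^a` and cross-contact correlation
#' `exp(-d / l)` (realised by a Cholesky factor of the distance-based
#' covariance), and (iii) the common-mode tones, identical on all
#' contacts. Output is bit-reproducible given (config, seed).
#'
#' @param arr an [electrode_array()].
#' @param config a [field_config()].
#' @param duration_s duration in seconds (>= 2).
#' @param fs sampling rate (default 3052 Hz, the acquisition rate).
#' @param seed RNG seed.
#' @return An `ieeg_recording`.
#' @export
simulate_field <- function(arr, config, duration_s, fs = 3052, seed = 1L) {
  stopifnot(inherits(arr, "electrode_array"), inherits(config, "field_config"))
  if (duration_s < 2) stop("invalid config: duration must be >= 2 s",
                           call. = FALSE)
  nt <- round(duration_s * fs)
  nc <- nrow(arr)
  pos <- positions(arr)
  tt <- (0:(nt - 1)) / fs
  x <- matrix(0, nc, nt)
  w <- config$waves
  if (nrow(w)) {
    lambda <- 1000 * w$speed_mps / w$freq_hz          # mm
    u <- cbind(cos(w$bearing_deg * pi / 180), sin(w$bearing_deg * pi / 180))
    beta <- sweep(pos[, 1:2, drop = FALSE] %*% t(u), 2L,
                  2 * pi / lambda, "*")                             # nc x J
    alpha <- outer(tt, 2 * pi * w$freq_hz)                           # nt x J
    alpha <- sweep(alpha, 2L, w$phase, "+")
    # cos(alpha - beta) = cos a cos b + sin a sin b
    A <- w$amplitude
    x <- x + t(cos(alpha) %*% (A * t(cos(beta))) +
               sin(alpha) %*% (A * t(sin(beta))))
  }
  ap <- config$aperiodic
  if (ap$power > 0) {
    x <- x + aperiodic_field(pos, nt, fs, ap, child_seed(seed, 1L))
  }
  cm <- config$common_mode
  if (length(cm$freq_hz)) {
    tone <- rep(0, nt)
    ph <- with_local_seed(child_seed(seed, 2L),
                          stats::runif(length(cm$freq_hz), 0, 2 * pi))
    for (i in seq_along(cm$freq_hz)) {
      tone <- tone + cm$amplitude[i] * cos(2 * pi * cm$freq_hz[i] * tt + ph[i])
    }
    x <- sweep(x, 2L, tone, "+")
  }
  new_recording(x, fs, arr$contact_id)
}

# spatially-coherent 1/f^a noise: white noise shaped in the frequency
# domain, then mixed across contacts by the Cholesky factor of
# exp(-distance / coherence).
aperiodic_field <- function(pos, nt, fs, ap, seed) {
  nc <- nrow(pos)
  d <- as.matrix(stats::dist(pos))
  C <- exp(-d / ap$coherence_mm)
  R <- tryCatch(chol(C), error = function(e) {
    warning("aperiodic covariance not positive definite; ridge added")
    chol(C + diag(1e-8, nc))
  })
  f_two <- pmin(0:(nt - 1), nt - (0:(nt - 1))) * fs / nt
  gain <- rep(0, nt)
  inband <- f_two >= ap$band[1] & f_two <= min(ap$band[2], fs / 2)
  gain[inband] <- sqrt(ap$power / f_two[inband]^ap$exponent * fs / 2)
  z <- with_local_seed(seed, matrix(stats::rnorm(nt * nc), nt, nc))
  chunk <- max(1L, floor(4e7 / nt))
  for (j0 in seq(1L, nc, by = chunk)) {
    j1 <- min(nc, j0 + chunk - 1L)
    zf <- stats::mvfft(z[, j0:j1, drop = FALSE]) * gain
    z[, j0:j1] <- Re(stats::mvfft(zf, inverse = TRUE)) / nt
  }
  t(z %*% R)
}

#' Plane-wave bipolar-to-referential power ratio (closed form)
#'
#' For a plane wave of spatial wavelength `lambda`, a bipolar pair of
#' separation `d` whose axis makes angle `theta` with the propagation
#' direction has difference-signal power `4 sin^2(pi d cos(theta) / lambda)`
#' times the single-electrode power: zero at zero separation, 1 at
#' `d cos(theta) = lambda / 6` (the reversal point), and a maximum of 4 at
#' half a wavelength (180 degrees of spatial phase).
#'
#' @param d_mm pair separation (mm).
#' @param lambda_mm spatial wavelength (mm).
#' @param theta_deg angle between pair axis and propagation (default 0).
#' @return Power ratio (vectorised over `d_mm`).
#' @export
analytic_pair_power_ratio <- function(d_mm, lambda_mm, theta_deg = 0) {
  stopifnot(lambda_mm > 0)
  4 * sin(pi * d_mm * cos(theta_deg * pi / 180) / lambda_mm)^2
}

#' Direction-averaged plane-wave power ratio
#'
#' Averaging `4 sin^2(pi d cos(theta)/lambda)` over uniformly distributed
#' in-plane pair orientations gives `2 (1 - J0(2 pi d / lambda))`: the
#' expected bipolar-to-referential ratio in an omnidirectional distance bin.
#'
#' @inheritParams analytic_pair_power_ratio
#' @return Power ratio (vectorised over `d_mm`).
#' @export
analytic_bin_power_ratio <- function(d_mm, lambda_mm) {
  2 * (1 - besselJ(2 * pi * d_mm / lambda_mm, 0))
}

#' Aperiodic-field bipolar power ratio
#'
#' Two contacts with correlation `exp(-d / l)` give a difference signal of
#' relative power `2 (1 - exp(-d / l))`: 0 at zero separation and 2 (i.e.
#' +100% power) in the independent-noise limit `d >> l`.
#'
#' @param d_mm pair separation (mm).
#' @param coherence_mm coherence length `l` (mm).
#' @return Power ratio.
#' @export
analytic_aperiodic_power_ratio <- function(d_mm, coherence_mm) {
  2 * (1 - exp(-d_mm / coherence_mm))
}

#' Reversal distance of a plane wave (grid scan)
#'
#' The smallest positive colinear separation at which bipolar power equals
#' single-electrode power, found by scanning the closed-form ratio on a
#' regular grid and locating the first upward crossing of 1
#' (analytically `lambda / 6`).
#'
#' @param lambda_mm spatial wavelength (mm).
#' @param step_mm grid step (default 0.01).
#' @param d_max_mm scan upper limit (default `lambda_mm / 2`).
#' @return List: `distance_mm`, `n_grid`.
#' @export
find_reversal_distance <- function(lambda_mm, step_mm = 0.01,
                                   d_max_mm = lambda_mm / 2) {
  d <- seq(step_mm, d_max_mm, by = step_mm)
  ratio <- analytic_pair_power_ratio(d, lambda_mm)
  hit <- which(ratio >= 1 - 1e-12)[1]
  if (is.na(hit)) stop("no reversal in scan range", call. = FALSE)
  list(distance_mm = d[hit], n_grid = length(d))
}

#' Attenuation-to-amplification transition frequency of a fixed pair
#'
#' With the dispersion rule `lambda(f) = v / f`, a pair of separation `d`
#' attenuates frequencies whose wavelength is long relative to `d` and
#' amplifies the rest; the crossing `4 sin^2(pi d f / (1000 v)) = 1` is
#' located on a frequency grid (analytically `1000 v / (6 d)` Hz).
#'
#' @param d_mm pair separation (mm).
#' @param speed_mps propagation speed (m/s).
#' @param f_grid frequency grid (default 2-200 Hz by 0.1).
#' @return List: `frequency_hz`, `n_grid`.
#' @export
find_transition_frequency <- function(d_mm, speed_mps = 0.72,
                                      f_grid = seq(2, 200, by = 0.1)) {
  ratio <- analytic_pair_power_ratio(d_mm, 1000 * speed_mps / f_grid)
  hit <- which(ratio >= 1 - 1e-12)[1]
  if (is.na(hit)) stop("no transition in frequency grid", call. = FALSE)
  list(frequency_hz = f_grid[hit], n_grid = length(f_grid))
}

#' Empirical bipolar-to-referential power ratio of recorded pairs
#'
#' Variance of the difference signal divided by the mean variance of the
#' two contributing referential channels; the time-domain counterpart of
#' the closed-form oracles.
#'
#' @param rec an `ieeg_recording`.
#' @param pairs a `bipolar_pairs` data frame.
#' @return Numeric vector, one ratio per pair.
#' @export
empirical_pair_power_ratio <- function(rec, pairs) {
  ix <- pair_channel_index(pairs, rec$channel_ids)
  vapply(seq_len(nrow(pairs)), function(i) {
    a <- rec$samples[ix$a[i], ]; b <- rec$samples[ix$c[i], ]
    stats::var(a - b) / mean(c(stats::var(a), stats::var(b)))
  }, 0)
}

#' IED event configuration
#'
#' @param n_events number of discharges to inject.
#' @param center_contact contact id receiving the full amplitude.
#' @param sigma_mm Gaussian spatial footprint SD (default 8).
#' @param amplitude_uv peak spike amplitude at the centre contact
#'   (default 400).
#' @param amp_jitter multiplicative amplitude jitter SD (fraction,
#'   default 0).
#' @param min_separation_s minimum event separation (default 1 s).
#' @return List of class `ied_config`.
#' @export
ied_config <- function(n_events, center_contact, sigma_mm = 8,
                       amplitude_uv = 400, amp_jitter = 0,
                       min_separation_s = 1) {
  stopifnot(n_events >= 0, sigma_mm > 0, amplitude_uv >= 0)
  structure(list(n_events = n_events, center_contact = center_contact,
                 sigma_mm = sigma_mm, amplitude_uv = amplitude_uv,
                 amp_jitter = amp_jitter,
                 min_separation_s = min_separation_s),
            class = "ied_config")
}

#' Interictal discharge template
#'
#' Biphasic sharp transient (about 70 ms) followed by a slower wave
#' (about 300 ms), peak-normalised to 1.
#'
#' @param fs sampling rate (Hz).
#' @return Numeric vector of template samples.
#' @export
ied_template <- function(fs) {
  t1 <- round(0.030 * fs); t2 <- round(0.040 * fs); t3 <- round(0.300 * fs)
  spike <- c(-sin(pi * seq_len(t1) / t1),
             0.9 * sin(pi * seq_len(t2) / t2))
  slow <- -0.35 * sin(pi * seq_len(t3) / t3)
  tpl <- c(spike, slow)
  tpl / max(abs(tpl))
}

#' Inject interictal discharges into a recording
#'
#' Adds the spike-and-wave template at randomly placed, non-overlapping
#' times (separation at least `min_separation_s`), with a Gaussian spatial
#' amplitude footprint `A exp(-d^2 / (2 sigma^2))` around the centre
#' contact, and returns matching onset/offset annotations.
#'
#' @param rec an `ieeg_recording`.
#' @param arr the matching [electrode_array()].
#' @param config an [ied_config()].
#' @param seed RNG seed.
#' @return List: `recording` (with IEDs added), `annotations`
#'   ([annotation_table()] with one `ied` row per event).
#' @export
inject_ieds <- function(rec, arr, config, seed = 1L) {
  stopifnot(inherits(config, "ied_config"))
  if (config$n_events == 0) {
    return(list(recording = rec, annotations = annotation_table()))
  }
  fs <- rec$fs
  tpl <- ied_template(fs) * config$amplitude_uv
  len <- length(tpl)
  ctr <- match(config$center_contact, arr$contact_id)
  if (is.na(ctr)) stop("invalid config: unknown center contact", call. = FALSE)
  d <- sqrt(rowSums(sweep(positions(arr), 2L,
                          positions(arr)[ctr, ], "-")^2))
  footprint <- exp(-d^2 / (2 * config$sigma_mm^2))
  # slot pitch covers the separation, the template, and the within-slot
  # jitter so consecutive events stay >= min_separation_s apart
  sep <- round(config$min_separation_s * fs) + len + fs
  max_start <- ncol(rec$samples) - len - 2 * fs
  slots <- floor(max_start / sep)
  if (slots < config$n_events) {
    stop("invalid config: recording too short for requested IED count",
         call. = FALSE)
  }
  pick <- with_local_seed(seed, {
    starts <- (sort(sample.int(slots, config$n_events)) - 1L) * sep +
      sample.int(fs, config$n_events, replace = TRUE)
    amps <- if (config$amp_jitter > 0)
      pmax(0.2, 1 + stats::rnorm(config$n_events, 0, config$amp_jitter))
      else rep(1, config$n_events)
    list(starts = starts, amps = amps)
  })
  x <- rec$samples
  ids <- match(rec$channel_ids, arr$contact_id)
  for (e in seq_len(config$n_events)) {
    s0 <- pick$starts[e] + fs                # leave an initial margin
    seg <- s0:(s0 + len - 1L)
    x[, seg] <- x[, seg] +
      outer(footprint[ids] * pick$amps[e], tpl)
  }
  ann <- annotation_table(onset_s = (pick$starts + fs - 1) / fs,
                          offset_s = (pick$starts + fs - 1 + len) / fs,
                          kind = "ied")
  list(recording = new_recording(x, fs, rec$channel_ids), annotations = ann)
}

#' Inject a task-window high-gamma power increase
#'
#' During each stimulus interval, the band-limited (`gain_band`) component
#' of every subset contact is scaled so its power is multiplied by `gain`
#' (implemented by adding `(sqrt(gain) - 1)` times the band-passed signal
#' inside the interval, with 50 ms cosine ramps at the edges). Overlapping
#' intervals are merged with a warning. Stimulus annotations are returned.
#'
#' @param rec an `ieeg_recording`.
#' @param subset_ids contact ids receiving the modulation.
#' @param intervals two-column matrix (onset_s, offset_s) of stimulus
#'   windows.
#' @param gain_band frequency band whose power is scaled (default 50-200).
#' @param gain multiplicative power gain (default 1.5).
#' @return List: `recording`, `annotations` (`stimulus` rows).
#' @export
inject_task_modulation <- function(rec, subset_ids, intervals,
                                   gain_band = c(50, 200), gain = 1.5) {
  intervals <- matrix(intervals, ncol = 2)
  if (any(intervals[, 1] > intervals[, 2]) ||
      any(intervals > rec_duration(rec))) {
    stop("invalid config: stimulus intervals outside recording", call. = FALSE)
  }
  o <- order(intervals[, 1])
  intervals <- intervals[o, , drop = FALSE]
  merged <- intervals[1, , drop = FALSE]
  for (i in seq_len(nrow(intervals))[-1]) {
    if (intervals[i, 1] <= merged[nrow(merged), 2]) {
      warning("overlapping stimulus intervals merged")
      merged[nrow(merged), 2] <- max(merged[nrow(merged), 2], intervals[i, 2])
    } else merged <- rbind(merged, intervals[i, ])
  }
  ann <- annotation_table(merged[, 1], merged[, 2], "stimulus")
  if (gain == 1) return(list(recording = rec, annotations = ann))
  fs <- rec$fs
  bf <- signal::butter(4, gain_band / (fs / 2), type = "pass")
  mask <- rep(0, ncol(rec$samples))
  ramp_n <- round(0.05 * fs)
  for (i in seq_len(nrow(merged))) {
    s0 <- floor(merged[i, 1] * fs) + 1L
    s1 <- min(ncol(rec$samples), ceiling(merged[i, 2] * fs))
    mask[s0:s1] <- 1
    up <- seq(0, 1, length.out = ramp_n)
    r0 <- s0:min(s1, s0 + ramp_n - 1L)
    mask[r0] <- pmin(mask[r0], up[seq_along(r0)])
    r1 <- max(s0, s1 - ramp_n + 1L):s1
    mask[r1] <- pmin(mask[r1], rev(up)[seq_along(r1)])
  }
  x <- rec$samples
  rows <- which(rec$channel_ids %in% subset_ids)
  for (ch in rows) {
    bp <- zero_phase_filter(bf, x[ch, ])
    x[ch, ] <- x[ch, ] + (sqrt(gain) - 1) * bp * mask
  }
  list(recording = new_recording(x, fs, rec$channel_ids), annotations = ann)
}
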