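#' Discrete prolate spheroidal (Slepian) tapers
#'
#' Computed from the symmetric tridiagonal formulation of the spectral
#' concentration problem: diagonal `((N-1-2t)/2)^2 cos(2*pi*W)`,
#' off-diagonal `t(N-t)/2`. The top `k` eigenvectors, normalised to unit
#' energy, are the tapers. Results are cached per `(n, nw, k)`.
#'
#' @param n taper length in samples.
#' @param nw time-bandwidth product (default 3).
#' @param k number of tapers (default 5; must satisfy `k <= 2*nw - 1`).
#' @return n x k matrix of tapers (columns), unit energy each.
#' @export
dpss_tapers <- local({
  cache <- new.env(parent = emptyenv())
  function(n, nw = 3, k = 5L) {
    if (k > 2 * nw - 1 + 1e-9) {
      stop("invalid config: need k <= 2*nw - 1 tapers", call. = FALSE)
    }
    key <- paste(n, nw, k, sep = "_")
    if (!is.null(cache[[key]])) return(cache[[key]])
    w <- nw / n
    t0 <- 0:(n - 1)
    diag_main <- ((n - 1 - 2 * t0) / 2)^2 * cos(2 * pi * w)
    diag_off <- (1:(n - 1)) * (n - 1:(n - 1)) / 2
    A <- matrix(0, n, n)
    A[cbind(1:n, 1:n)] <- diag_main
    A[cbind(1:(n - 1), 2:n)] <- diag_off
    A[cbind(2:n, 1:(n - 1))] <- diag_off
    ev <- eigen(A, symmetric = TRUE)
    h <- ev$vectors[, seq_len(k), drop = FALSE]
    h <- sweep(h, 2L, sqrt(colSums(h^2)), "/")
    # sign convention: symmetric tapers positive mean; antisymmetric positive
    # initial lobe (irrelevant for power, fixed for reproducibility)
    for (j in seq_len(k)) {
      s <- sum(h[, j])
      if (abs(s) > 1e-8) { if (s < 0) h[, j] <- -h[, j] }
      else if (h[which.max(abs(h[, j])), j] < 0) h[, j] <- -h[, j]
    }
    cache[[key]] <- h
    h
  }
})

#' @keywords internal
new_spectra <- function(power, freq, scale, n_windows, series_ids = NULL) {
  power <- as.matrix(power)
  if (is.null(series_ids)) series_ids <- rownames(power)
  if (is.null(series_ids)) series_ids <- paste0("s", seq_len(nrow(power)))
  rownames(power) <- series_ids
  structure(list(power = power, freq = freq, scale = scale,
                 n_windows = n_windows, series_ids = series_ids),
            class = "bprr_spectra")
}

#' @export
print.bprr_spectra <- function(x, ...) {
  cat(sprintf("<bprr_spectra> %d series x %d freqs (%g-%g Hz), scale=%s, %d window(s)\n",
              nrow(x$power), length(x$freq), min(x$freq), max(x$freq),
              x$scale, x$n_windows))
  invisible(x)
}

# samples x channels matrix of window j (robust to single-channel sets)
window_matrix <- function(w, j) {
  m <- w$data[, , j, drop = FALSE]
  dim(m) <- dim(m)[1:2]
  t(m)
}

# tapered FFT rows for the analysis band. Returns frequency grid and a
# function mapping a (samples x channels) window matrix to a
# freq x channels x tapers complex array.
taper_fft_plan <- function(n, fs, fmin, fmax, nw, k, demean = TRUE) {
  h <- dpss_tapers(n, nw, k)
  df <- fs / n
  bins <- which((0:(n - 1)) * df >= fmin - 1e-9 & (0:(n - 1)) * df <= fmax + 1e-9)
  freq <- (bins - 1) * df
  list(freq = freq, k = k, fs = fs,
       fft = function(x) {
         x <- as.matrix(x)
         if (demean) x <- sweep(x, 2L, colMeans(x), "-")
         out <- array(0i, dim = c(length(bins), ncol(x), k))
         for (j in seq_len(k)) {
           out[, , j] <- stats::mvfft(x * h[, j])[bins, , drop = FALSE]
         }
         out
       })
}

#' Multitaper power spectral density of 1 s windows
#'
#' Slepian multitaper PSD per channel on the 2-200 Hz grid (1 Hz spacing
#' when windows are 1 s). Power is one-sided density in signal-units^2/Hz;
#' averaging across windows and tapers is an arithmetic mean on the linear
#' power scale.
#'
#' @param w an `ieeg_windows` object (windows of `fs` samples).
#' @param nw time-bandwidth product (default 3).
#' @param k number of tapers (default 5).
#' @param fmin,fmax analysis band (default 2-200 Hz).
#' @param demean subtract each window's mean before tapering (default TRUE).
#' @return A `bprr_spectra` (scale `"linear"`), channels x frequencies.
#' @export
multitaper_psd <- function(w, nw = 3, k = 5L, fmin = 2, fmax = 200,
                           demean = TRUE) {
  stopifnot(inherits(w, "ieeg_windows"))
  n <- dim(w$data)[2]
  if (n < w$fs) stop("invalid window: shorter than 1 s", call. = FALSE)
  plan <- taper_fft_plan(n, w$fs, fmin, fmax, nw, k, demean)
  acc <- matrix(0, length(plan$freq), dim(w$data)[1])
  for (j in seq_len(n_windows(w))) {
    ft <- plan$fft(window_matrix(w, j))
    acc <- acc + rowMeans(Mod(ft)^2, dims = 2L)
  }
  pow <- t(acc / n_windows(w)) * 2 / w$fs   # one-sided density
  new_spectra(pow, plan$freq, "linear", n_windows(w), w$channel_ids)
}

#' Multitaper PSD of bipolar pairs, computed from referential windows
#'
#' Exploits linearity of the tapered Fourier transform: the transform of
#' the anode-minus-cathode signal is the difference of the channel
#' transforms, so per-pair spectra are formed without materialising the
#' bipolar time series. Identical (to rounding) to
#' `multitaper_psd(apply_bipolar(w, pairs), ...)`.
#'
#' @inheritParams multitaper_psd
#' @param pairs a `bipolar_pairs` data frame over the channels of `w`.
#' @param per_window return per-window power as a freq x pair x window array
#'   (attribute `"per_window"`) in addition to the average (default FALSE).
#' @return A `bprr_spectra`, pairs x frequencies.
#' @export
bipolar_psd <- function(w, pairs, nw = 3, k = 5L, fmin = 2, fmax = 200,
                        demean = TRUE, per_window = FALSE) {
  stopifnot(inherits(w, "ieeg_windows"))
  ix <- pair_channel_index(pairs, w$channel_ids)
  n <- dim(w$data)[2]
  plan <- taper_fft_plan(n, w$fs, fmin, fmax, nw, k, demean)
  nf <- length(plan$freq); np <- nrow(pairs); nwin <- n_windows(w)
  acc <- matrix(0, nf, np)
  pw <- if (per_window) array(0, dim = c(nf, np, nwin)) else NULL
  for (j in seq_len(nwin)) {
    ft <- plan$fft(window_matrix(w, j))
    pj <- matrix(0, nf, np)
    for (tp in seq_len(k)) {
      pj <- pj + Mod(ft[, ix$a, tp, drop = FALSE] -
                     ft[, ix$c, tp, drop = FALSE])[, , 1L]^2
    }
    pj <- pj / k
    acc <- acc + pj
    if (per_window) pw[, , j] <- pj * 2 / w$fs
  }
  out <- new_spectra(t(acc / nwin) * 2 / w$fs, plan$freq, "linear", nwin,
                     paste0(pairs$anode_id, "-", pairs$cathode_id))
  if (per_window) attr(out, "per_window") <- pw
  out
}

#' Canonical frequency band table
#'
#' delta 2-4, theta 4-8, alpha 8-13, beta 13-25, gamma 25-50,
#' high gamma 50-200 Hz.
#'
#' @return data frame with columns `band`, `f_low`, `f_high`.
#' @export
band_table <- function() {
  data.frame(band = c("delta", "theta", "alpha", "beta", "gamma", "high_gamma"),
             f_low = c(2, 4, 8, 13, 25, 50),
             f_high = c(4, 8, 13, 25, 50, 200),
             stringsAsFactors = FALSE)
}

band_mean_power <- function(spec, f_low, f_high) {
  sel <- spec$freq >= f_low & spec$freq <= f_high
  rowMeans(spec$power[, sel, drop = FALSE])
}

#' Rebase spectra by a subject's referential low-frequency level
#'
#' Converts all spectra to log10 power and subtracts a single per-subject
#' scalar: the median over 2-10 Hz of the electrode-averaged referential
#' log-spectrum. This puts curves from different subjects on a common
#' relative scale while preserving all power differences between curves.
#'
#' @param spectra a `bprr_spectra` (any linear-scale spectra to rebase) or a
#'   list of them.
#' @param referential the subject's referential `bprr_spectra`
#'   (linear scale, must cover 2-10 Hz).
#' @param log_scale rebase in log10 power (default TRUE); FALSE subtracts on
#'   the linear scale (sensitivity analysis only).
#' @return Rebased spectra (scale `"rebased_log"`), same shape as `spectra`.
#' @export
rebase_spectra <- function(spectra, referential, log_scale = TRUE) {
  if (!inherits(referential, "bprr_spectra") || nrow(referential$power) == 0) {
    stop("invalid input: empty referential spectrum set", call. = FALSE)
  }
  sel <- referential$freq >= 2 & referential$freq <= 10
  if (!any(sel)) stop("invalid input: referential must cover 2-10 Hz",
                      call. = FALSE)
  ref_curve <- colMeans(referential$power[, sel, drop = FALSE])
  offset <- if (log_scale) stats::median(log10(ref_curve)) else
    stats::median(ref_curve)
  rebase1 <- function(sp) {
    v <- if (log_scale) log10(sp$power) else sp$power
    new_spectra(v - offset, sp$freq, "rebased_log", sp$n_windows,
                sp$series_ids)
  }
  if (inherits(spectra, "bprr_spectra")) rebase1(spectra)
  else lapply(spectra, rebase1)
}

#' Export spectra as TSV (+ metadata JSON)
#'
#' Rows are channels/pairs, columns `f<freq>`; a companion
#' `<path>.json` stores scale, window count, and taper parameters.
#'
#' @param spec `bprr_spectra`.
#' @param path TSV path.
#' @param params optional named list merged into the metadata JSON.
#' @export
write_spectra_tsv <- function(spec, path, params = list()) {
  m <- as.data.frame(spec$power)
  names(m) <- paste0("f", spec$freq)
  out <- cbind(data.frame(series = spec$series_ids, stringsAsFactors = FALSE), m)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(c(list(scale = spec$scale, n_windows = spec$n_windows),
                         params),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}
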