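#' Anti-alias filter and downsample a recording
#'
#' Applies a zero-phase (forward-backward) 4th-order Butterworth low-pass
#' filter below `cutoff`, then resamples to `target_fs` by frequency-domain
#' (ideal low-pass) interpolation, which handles the non-integer ratio
#' between the clinical acquisition rate (3052 Hz) and the analysis rate
#' (512 Hz) exactly.
#'
#' @param rec an `ieeg_recording`.
#' @param cutoff low-pass cutoff in Hz (default 255).
#' @param target_fs output sampling rate in Hz (default 512).
#' @param order Butterworth order applied in each direction (default 4).
#' @return A filtered `ieeg_recording` at `target_fs`.
#' @export
lowpass_downsample <- function(rec, cutoff = 255, target_fs = 512, order = 4L) {
  stopifnot(inherits(rec, "ieeg_recording"))
  if (target_fs > rec$fs) {
    stop("invalid config: target_fs exceeds recording rate", call. = FALSE)
  }
  if (rec$fs <= 2 * cutoff) {
    stop("invalid config: recording rate must exceed twice the cutoff",
         call. = FALSE)
  }
  bf <- signal::butter(order, cutoff / (rec$fs / 2), type = "low")
  filt <- t(apply(rec$samples, 1L, function(x) zero_phase_filter(bf, x)))
  if (target_fs == rec$fs) {
    return(new_recording(filt, rec$fs, rec$channel_ids))
  }
  n_new <- round(ncol(filt) * target_fs / rec$fs)
  out <- t(apply(filt, 1L, fft_resample, n_new = n_new))
  new_recording(out, target_fs, rec$channel_ids)
}

# forward-backward filtering with odd-reflection end padding to suppress
# edge transients (the padding scheme scipy/matlab filtfilt use).
zero_phase_filter <- function(bf, x) {
  np <- min(length(x) - 1L, 100L * (max(length(bf$b), length(bf$a)) - 1L))
  head_pad <- 2 * x[1] - x[(np + 1):2]
  tail_pad <- 2 * x[length(x)] - x[(length(x) - 1):(length(x) - np)]
  y <- signal::filtfilt(bf, c(head_pad, x, tail_pad))
  y[(np + 1):(np + length(x))]
}

# frequency-domain resampling (ideal low-pass interpolation onto n_new
# samples); exact for band-limited signals, preserves DC exactly.
fft_resample <- function(x, n_new) {
  n <- length(x)
  if (n_new == n) return(x)
  X <- stats::fft(x)
  Y <- complex(n_new)
  half <- min(floor(n_new / 2), floor(n / 2))
  Y[1] <- X[1]
  if (half >= 1) {
    Y[2:(half + 1)] <- X[2:(half + 1)]
    Y[n_new - (1:half) + 1] <- X[n - (1:half) + 1]
  }
  if (n_new %% 2 == 0 && half == n_new / 2) {
    Y[half + 1] <- Re(Y[half + 1])   # Nyquist bin must be real
  }
  Re(stats::fft(Y, inverse = TRUE)) / n
}

#' Notch out mains interference
#'
#' Zero-phase 2nd-order Butterworth band-stop sections with a 2 Hz stop band
#' centred on the mains frequency and each requested harmonic.
#'
#' @param rec an `ieeg_recording`.
#' @param base mains frequency in Hz (default 60).
#' @param harmonics harmonic frequencies also notched (default 120/180/240).
#' @param bw stop-band width in Hz (default 2).
#' @return Filtered `ieeg_recording`.
#' @export
notch_line_noise <- function(rec, base = 60, harmonics = c(120, 180, 240),
                             bw = 2) {
  stopifnot(inherits(rec, "ieeg_recording"))
  freqs <- c(base, harmonics)
  if (any(freqs >= rec$fs / 2)) {
    stop("invalid config: notch frequency at or above Nyquist", call. = FALSE)
  }
  x <- rec$samples
  for (f0 in freqs) {
    bf <- signal::butter(2, c(f0 - bw / 2, f0 + bw / 2) / (rec$fs / 2),
                         type = "stop")
    x <- t(apply(x, 1L, function(v) zero_phase_filter(bf, v)))
  }
  new_recording(x, rec$fs, rec$channel_ids)
}

#' Annotation table constructor
#'
#' @param onset_s,offset_s event interval in seconds (onset <= offset).
#' @param kind one of `"ied"`, `"artifact"`, `"stimulus"` per row.
#' @return data frame of class `annotation_table`.
#' @export
annotation_table <- function(onset_s = numeric(), offset_s = numeric(),
                             kind = character()) {
  stopifnot(length(onset_s) == length(offset_s),
            length(kind) %in% c(1L, length(onset_s)) || length(onset_s) == 0)
  if (any(offset_s < onset_s) || any(onset_s < 0)) {
    stop("invalid annotations: need 0 <= onset_s <= offset_s", call. = FALSE)
  }
  kind <- rep_len(as.character(kind), length(onset_s))
  bad <- setdiff(unique(kind), c("ied", "artifact", "stimulus"))
  if (length(bad)) {
    stop("invalid annotations: unknown kind ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  structure(data.frame(onset_s = onset_s, offset_s = offset_s, kind = kind,
                       stringsAsFactors = FALSE),
            class = c("annotation_table", "data.frame"))
}

#' Read / write annotations (TSV: onset_s, offset_s, kind)
#' @param path file path.
#' @export
read_annotations <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  annotation_table(df$onset_s, df$offset_s, df$kind)
}

#' @rdname read_annotations
#' @param ann annotation table to write.
#' @export
write_annotations <- function(ann, path) {
  utils::write.table(as.data.frame(ann), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

windows_overlapping <- function(starts_s, len_s, ann) {
  # returns logical: does window [s, s+len) overlap any row of ann?
  if (nrow(ann) == 0) return(rep(FALSE, length(starts_s)))
  sapply(starts_s, function(s) {
    any(ann$onset_s < s + len_s & ann$offset_s > s)
  })
}

#' Parse a recording into labelled 1 s baseline windows
#'
#' Consecutive non-overlapping 1 s windows starting at t = 0. Windows
#' overlapping any IED or artifact annotation are removed entirely; windows
#' overlapping a stimulus annotation are kept and labelled `"stimulus"`, the
#' rest are `"baseline"`.
#'
#' @param rec an `ieeg_recording` (>= 1 s long).
#' @param ann an [annotation_table()].
#' @return An `ieeg_windows` object.
#' @export
parse_baseline_windows <- function(rec, ann = annotation_table()) {
  stopifnot(inherits(rec, "ieeg_recording"))
  fs <- rec$fs
  n_win <- floor(ncol(rec$samples) / fs)
  if (n_win < 1) stop("recording shorter than 1 s", call. = FALSE)
  starts_s <- seq_len(n_win) - 1
  drop <- windows_overlapping(starts_s, 1,
                              ann[ann$kind %in% c("ied", "artifact"), ,
                                  drop = FALSE])
  stim <- windows_overlapping(starts_s, 1,
                              ann[ann$kind == "stimulus", , drop = FALSE])
  keep <- which(!drop)
  dat <- array(0, dim = c(nrow(rec$samples), fs, length(keep)))
  for (j in seq_along(keep)) {
    s0 <- starts_s[keep[j]] * fs
    dat[, , j] <- rec$samples[, (s0 + 1):(s0 + fs), drop = FALSE]
  }
  info <- data.frame(start_sample = as.integer(starts_s[keep] * fs + 1),
                     label = ifelse(stim[keep], "stimulus", "baseline"),
                     stringsAsFactors = FALSE)
  new_windows(dat, fs, rec$channel_ids, info)
}

#' Extract 1 s windows centred on each epileptiform discharge
#'
#' Each IED annotation is aligned to the sample, within its annotated
#' interval, with the maximum absolute first difference across channels
#' (maximum absolute slope; ties broken by the earliest sample). A 1 s
#' window (0.5 s before and after) is cut around that sample; events too
#' close to a recording edge are dropped with a warning.
#'
#' @param rec an `ieeg_recording`.
#' @param ann an [annotation_table()]; only `kind == "ied"` rows are used.
#' @return An `ieeg_windows` object with label `"ied"`.
#' @export
center_ied_windows <- function(rec, ann) {
  stopifnot(inherits(rec, "ieeg_recording"))
  fs <- rec$fs
  ieds <- ann[ann$kind == "ied", , drop = FALSE]
  half <- floor(fs / 2)
  len <- as.integer(fs)
  centers <- integer(0)
  for (i in seq_len(nrow(ieds))) {
    s0 <- max(2L, floor(ieds$onset_s[i] * fs) + 1L)
    s1 <- min(ncol(rec$samples), ceiling(ieds$offset_s[i] * fs) + 1L)
    if (s1 - s0 < 1L) next
    seg <- rec$samples[, (s0 - 1L):s1, drop = FALSE]
    slope <- abs(seg[, -1L, drop = FALSE] - seg[, -ncol(seg), drop = FALSE])
    mx <- apply(slope, 2L, max)          # max across channels, per sample
    centers <- c(centers, s0 - 1L + which.max(mx))
  }
  ok <- centers - half >= 1L & centers - half + len - 1L <= ncol(rec$samples)
  if (any(!ok)) {
    warning(sprintf("%d IED window(s) dropped: too close to recording edge",
                    sum(!ok)))
  }
  centers <- centers[ok]
  dat <- array(0, dim = c(nrow(rec$samples), len, length(centers)))
  for (j in seq_along(centers)) {
    s0 <- centers[j] - half
    dat[, , j] <- rec$samples[, s0:(s0 + len - 1L), drop = FALSE]
  }
  info <- data.frame(start_sample = as.integer(centers - half),
                     label = rep("ied", length(centers)),
                     stringsAsFactors = FALSE)
  new_windows(dat, fs, rec$channel_ids, info)
}

#' Read / write a recording as flat 32-bit binary with a JSON sidecar
#'
#' The sidecar (`<path>.json`) records `fs`, `n_channels`, `channel_ids`,
#' `dtype` (`"float32"`) and `order` (`"channel_major"`: all samples of
#' channel 1, then channel 2, ...).
#'
#' @param path binary file path (sidecar at `paste0(path, ".json")`).
#' @return `ieeg_recording` for the reader; invisibly `path` for the writer.
#' @export
read_recording_bin <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  n <- file.info(path)$size / 4
  x <- readBin(path, "numeric", n = n, size = 4)
  m <- matrix(x, nrow = meta$n_channels, byrow = TRUE)
  new_recording(m, meta$fs, meta$channel_ids)
}

#' @rdname read_recording_bin
#' @param rec recording to write.
#' @export
write_recording_bin <- function(rec, path) {
  writeBin(as.vector(t(rec$samples)), path, size = 4)
  jsonlite::write_json(list(fs = rec$fs, n_channels = nrow(rec$samples),
                            channel_ids = rec$channel_ids,
                            dtype = "float32", order = "channel_major"),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}
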