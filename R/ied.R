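#' Line-length transform
#'
#' The instantaneous line length is the absolute first difference of the
#' signal per sample (the first sample repeats the second, keeping the
#' sample count). Windowed variants are the centred moving sum of the
#' absolute first difference over `window_ms`; edge samples use the
#' available partial window and are flagged in the `"partial_edge"`
#' attribute. Line length accentuates sharp, high-slope epileptiform
#' activity; it is invariant to constant offsets and scales linearly with
#' amplitude.
#'
#' @param x numeric channel-by-sample matrix (or vector).
#' @param fs sampling rate in Hz.
#' @param window_ms `"instantaneous"` (default) or a window length in ms
#'   (the study used 100, 40, 20 ms and instantaneous).
#' @return Matrix of the same shape as `x`, values >= 0.
#' @export
line_length_transform <- function(x, fs, window_ms = "instantaneous") {
  vec <- is.null(dim(x))
  x <- rbind(x)
  d <- abs(x[, -1L, drop = FALSE] - x[, -ncol(x), drop = FALSE])
  d <- cbind(d[, 1L, drop = FALSE], d)      # per-sample |first difference|
  if (!identical(window_ms, "instantaneous")) {
    wlen <- max(1L, round(as.numeric(window_ms) / 1000 * fs))
    if (wlen > ncol(x)) stop("window_ms longer than the signal block",
                             call. = FALSE)
    half_l <- floor((wlen - 1) / 2); half_r <- wlen - 1L - half_l
    cs <- cbind(0, t(apply(d, 1L, cumsum)))
    n <- ncol(x)
    lo <- pmax(1L, seq_len(n) - half_l)
    hi <- pmin(n, seq_len(n) + half_r)
    d <- cs[, hi + 1L, drop = FALSE] - cs[, lo, drop = FALSE]
    attr(d, "partial_edge") <- seq_len(n) - half_l < 1L |
      seq_len(n) + half_r > n
  }
  if (vec) d[1L, ] else d
}

#' High- and low-density subsampled bipolar schemes
#'
#' Every other contact of each contact line is a "base electrode"
#' (odd positions). The high-density scheme pairs each base with its first
#' adjacent contact (one pitch away); the low-density scheme pairs the same
#' base with its second adjacent contact (two pitches away). Both schemes
#' share identical base electrodes; pairs whose partner falls off the line
#' are dropped.
#'
#' @param arr an [electrode_array()].
#' @return List with `high` and `low` `bipolar_pairs` (scheme `"ordinal"`,
#'   skips 1 and 2).
#' @export
build_density_schemes <- function(arr) {
  stopifnot(inherits(arr, "electrode_array"))
  hi <- list(); lo <- list()
  for (line in component_lines(arr)) {
    n <- length(line)
    if (n < 3) next
    base <- seq(1L, n, by = 2L)
    pitch <- arr$pitch_mm[line[1]]
    add <- function(skip) {
      i <- base[base + skip <= n]
      a <- line[i]; c_ <- line[i + skip]
      keep <- !arr$bad[a] & !arr$bad[c_]
      if (!any(keep)) return(NULL)
      data.frame(anode = a[keep], cathode = c_[keep],
                 component_id = arr$component_id[a[keep]],
                 distance_mm = skip * pitch, ordinal_skip = skip,
                 stringsAsFactors = FALSE)
    }
    hi[[length(hi) + 1L]] <- add(1L)
    lo[[length(lo) + 1L]] <- add(2L)
  }
  mk <- function(lst) {
    df <- if (length(lst)) do.call(rbind, lst) else
      data.frame(anode = integer(), cathode = integer(),
                 component_id = character(), distance_mm = numeric(),
                 ordinal_skip = integer(), stringsAsFactors = FALSE)
    df$anode_id <- arr$contact_id[df$anode]
    df$cathode_id <- arr$contact_id[df$cathode]
    new_bipolar_pairs(df, scheme = "ordinal")
  }
  list(high = mk(hi), low = mk(lo))
}

#' IED inclusion rule
#'
#' Participants contribute to the IED analysis only when enough IED windows
#' are available (default 50).
#'
#' @param n_ied number of detected IED windows.
#' @param min_ied inclusion threshold (default 50).
#' @return TRUE/FALSE; FALSE logs a message with the reason.
#' @export
ied_inclusion <- function(n_ied, min_ied = 50L) {
  if (n_ied < min_ied) {
    message(sprintf("IED analysis skipped: %d IED windows < %d required",
                    n_ied, min_ied))
    return(FALSE)
  }
  TRUE
}

#' Channel-wise cluster permutation test of IED vs baseline line length
#'
#' Per bipolar channel, line-length-transformed IED-centred windows are
#' compared with baseline windows sample-by-sample; temporal clusters of
#' contiguous supra-threshold samples are tested against a permutation
#' null of the maximum cluster mass, and channel-level p-values (smallest
#' cluster p per channel) are BH-FDR corrected across channels.
#'
#' @param ied_w,base_w `ieeg_windows` on the same (bipolar) channels.
#' @param fs sampling rate; defaults to `ied_w$fs`.
#' @param window_ms line-length window (`"instantaneous"`, 100, 40, 20).
#' @param n_perm permutations per channel (default 1000).
#' @param alpha cluster and FDR level (default 0.05).
#' @param alpha_cell cluster-forming alpha (default 0.05).
#' @param seed RNG seed.
#' @param match_baseline randomly subsample baseline windows to the IED
#'   window count before testing (default TRUE).
#' @return List of class `ied_cluster_result`: `channels` data frame
#'   (`channel`, `p`, `p_fdr`, `significant`, `sig_samples`), `sig_masks`
#'   (channel x sample logical matrix of FDR-surviving clusters), `fs`,
#'   `window_ms`.
#' @export
ied_channel_cluster_test <- function(ied_w, base_w, window_ms = "instantaneous",
                                     n_perm = 1000L, alpha = 0.05,
                                     alpha_cell = 0.05, seed = 1L,
                                     match_baseline = TRUE) {
  stopifnot(identical(ied_w$channel_ids, base_w$channel_ids),
            ied_w$fs == base_w$fs)
  if (n_perm < 100L) stop("invalid config: n_perm must be >= 100",
                          call. = FALSE)
  n_ied <- n_windows(ied_w); n_base <- n_windows(base_w)
  if (min(n_ied, n_base) < 20L) {
    warning(sprintf("fewer than 20 windows in a condition (%d IED, %d baseline)",
                    n_ied, n_base))
  }
  if (match_baseline && n_base > n_ied) {
    pick <- with_local_seed(child_seed(seed, 777L), sample.int(n_base, n_ied))
    base_w <- select_windows(base_w, index = sort(pick))
  }
  fs <- ied_w$fs
  nch <- length(ied_w$channel_ids); nsamp <- dim(ied_w$data)[2]
  pvals <- rep(1, nch)
  masks <- vector("list", nch)
  for (ch in seq_len(nch)) {
    # rows = windows, columns = samples; line length runs along samples
    xi <- line_length_transform(t(ied_w$data[ch, , ]), fs, window_ms)
    xb <- line_length_transform(t(base_w$data[ch, , ]), fs, window_ms)
    res <- suppressWarnings(
      cluster_perm_test(xi, xb, adjacency = "linear", n_perm = n_perm,
                        alpha_cell = alpha_cell, alpha = alpha,
                        seed = child_seed(seed, ch)))
    pvals[ch] <- if (nrow(res$clusters)) min(res$clusters$p) else 1
    masks[[ch]] <- res
  }
  fdr <- bh_fdr(pvals, alpha)
  sig_masks <- matrix(FALSE, nch, nsamp)
  if (any(fdr$reject)) {
    # clusters surviving the channel-level FDR: on rejected channels, mark
    # clusters whose p is at or below the largest rejected channel p
    thr_p <- max(pvals[fdr$reject])
    for (ch in which(fdr$reject)) {
      res <- masks[[ch]]
      for (i in seq_len(nrow(res$clusters))) {
        if (res$clusters$p[i] <= thr_p) {
          sig_masks[ch, abs(res$cluster_id) == res$clusters$id[i]] <- TRUE
        }
      }
    }
  }
  channels <- data.frame(channel = ied_w$channel_ids, p = pvals,
                         p_fdr = fdr$p_adjusted,
                         significant = fdr$reject & rowSums(sig_masks) > 0,
                         sig_samples = rowSums(sig_masks),
                         stringsAsFactors = FALSE)
  structure(list(channels = channels, sig_masks = sig_masks, fs = fs,
                 window_ms = window_ms),
            class = "ied_cluster_result")
}

#' Spatio-temporal extent of detected IEDs
#'
#' Per-channel significant duration (count of FDR-surviving significant
#' samples times 1000/fs, in ms), the mean width over significant channels,
#' and the number of channels involved.
#'
#' @param result an `ied_cluster_result`.
#' @param density_condition optional label (`"high"`/`"low"`).
#' @param width one of `"mean"` (default) or `"max"`: summary of
#'   per-channel durations over significant channels.
#' @return List of class `ied_extent`: `per_channel_ms`,
#'   `n_significant_channels`, `mean_width_ms`, `density_condition`.
#' @export
ied_extent_metrics <- function(result, density_condition = NA_character_,
                               width = c("mean", "max")) {
  width <- match.arg(width)
  dur <- result$channels$sig_samples * 1000 / result$fs
  sig <- result$channels$significant
  mw <- if (any(sig)) {
    if (width == "mean") mean(dur[sig]) else max(dur[sig])
  } else 0
  structure(list(per_channel_ms = stats::setNames(dur,
                                                  result$channels$channel),
                 n_significant_channels = sum(sig),
                 mean_width_ms = mw,
                 density_condition = density_condition),
            class = "ied_extent")
}

#' Compare IED extent between high- and low-density schemes
#'
#' Paired Wilcoxon signed-rank tests of per-IED extent metrics between the
#' two density conditions, with a Bonferroni-adjusted per-comparison
#' significance threshold `0.05 / n_conditions` across line-length
#' conditions (0.0125 for the four window lengths studied).
#'
#' @param high,low data frames (or lists of `ied_extent`) with paired rows
#'   per IED and columns/fields `mean_width_ms`, `n_significant_channels`.
#' @param metrics metrics to compare.
#' @param n_conditions number of line-length conditions sharing the family
#'   alpha (default 4).
#' @param family_alpha family-wise alpha (default 0.05).
#' @return Data frame: `metric`, `n_pairs`, `median_high`, `median_low`,
#'   `effect_size`, `p`, `threshold`, `significant`.
#' @export
compare_density_conditions <- function(high, low,
                                       metrics = c("mean_width_ms",
                                                   "n_significant_channels"),
                                       n_conditions = 4L,
                                       family_alpha = 0.05) {
  as_df <- function(x) {
    if (is.data.frame(x)) return(x)
    do.call(rbind, lapply(x, function(e)
      data.frame(mean_width_ms = e$mean_width_ms,
                 n_significant_channels = e$n_significant_channels)))
  }
  high <- as_df(high); low <- as_df(low)
  stopifnot(nrow(high) == nrow(low))
  if (nrow(high) < 6) {
    warning("fewer than 6 paired observations; signed-rank test is weak")
  }
  thr <- family_alpha / n_conditions
  rows <- lapply(metrics, function(m) {
    d <- high[[m]] - low[[m]]
    if (all(d == 0)) {
      p <- 1; es <- 0
    } else {
      p <- suppressWarnings(stats::wilcox.test(d, exact = TRUE)$p.value)
      es <- rank_biserial(d)
    }
    data.frame(metric = m, n_pairs = length(d),
               median_high = stats::median(high[[m]]),
               median_low = stats::median(low[[m]]),
               effect_size = es, p = p, threshold = thr,
               significant = p < thr, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
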