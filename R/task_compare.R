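# Stimulus-vs-baseline spectral contrast over frequency x distance with
# cluster-based permutation significance.

# per-window log10 bin-averaged power, z-scored by frequency across bins.
# The normalisation is a fixed affine per frequency row: mean and population
# SD pooled over (bin, window) values, applied identically to every window.
# A per-window normalisation would delete any distance-uniform condition
# effect from the contrast, and a grand-mean-only SD degenerates when power
# is flat across bins; pooling windows keeps the scale well-defined.
# returns list(obs = window x cell matrix, freq, centers, bins_used)
window_bin_maps <- function(w, pairs, nw = 3, k = 5L, fmin = 2, fmax = 200) {
  sp <- bipolar_psd(w, pairs, nw = nw, k = k, fmin = fmin, fmax = fmax,
                    per_window = TRUE)
  pw <- attr(sp, "per_window")           # freq x pair x window
  mb <- map_bins(pairs)
  populated <- mb$bins[mb$bins %in% unique(pairs$bin_index)]
  nf <- length(sp$freq); nb <- length(populated); nwin <- dim(pw)[3]
  logmaps <- array(NA_real_, dim = c(nf, nb, nwin))
  for (j in seq_len(nb)) {
    sel <- which(pairs$bin_index == populated[j])
    for (jw in seq_len(nwin)) {
      logmaps[, j, jw] <- log10(rowMeans(pw[, sel, jw, drop = FALSE]))
    }
  }
  flat <- matrix(logmaps, nf)            # nf x (nb * nwin)
  mu <- rowMeans(flat)
  sd_pop <- sqrt(rowMeans((flat - mu)^2))
  sd_pop[sd_pop == 0] <- 1
  obs <- matrix(NA_real_, nwin, nf * nb)
  for (jw in seq_len(nwin)) {
    obs[jw, ] <- as.vector((logmaps[, , jw] - mu) / sd_pop)
  }
  list(obs = obs, freq = sp$freq,
       centers = mb$centers[match(populated, mb$bins)],
       bins = populated)
}

#' Stimulus-minus-baseline distance-frequency contrast
#'
#' Restricts the pair set to the designated electrode subset (e.g. superior
#' temporal gyrus contacts) and to distances at or below `max_distance_mm`,
#' computes per-window bin-averaged log10 power z-scored by frequency
#' across bins, and contrasts the stimulus-window mean against the
#' baseline-window mean per frequency-by-bin cell.
#'
#' @param w an `ieeg_windows` with both `"stimulus"` and `"baseline"` labels.
#' @param pairs binned `bipolar_pairs` over the channels of `w`.
#' @param arr optional [electrode_array()]; when given, pairs are restricted
#'   to those whose both contacts have `subset = TRUE`.
#' @param max_distance_mm largest pair distance tested (default 40).
#' @param nw,k multitaper parameters.
#' @return List of class `condition_contrast`: `diff_map` (a
#'   `distance_map`, stat `"condition_difference"`), `stim`/`base`
#'   observation matrices (windows x cells) for permutation testing,
#'   `freq`, `centers`.
#' @export
condition_difference_map <- function(w, pairs, arr = NULL,
                                     max_distance_mm = 40, nw = 3, k = 5L) {
  labs <- unique(w$info$label)
  if (!all(c("stimulus", "baseline") %in% labs)) {
    stop("invalid input: need windows of both conditions", call. = FALSE)
  }
  keep <- pairs$distance_mm <= max_distance_mm
  if (!is.null(arr)) {
    sub_ids <- arr$contact_id[arr$subset]
    keep <- keep & pairs$anode_id %in% sub_ids & pairs$cathode_id %in% sub_ids
  }
  pairs_sub <- new_bipolar_pairs(as.data.frame(pairs)[keep, , drop = FALSE],
                                 scheme = attr(pairs, "scheme"),
                                 bin_width_mm = attr(pairs, "bin_width_mm"),
                                 range_mm = attr(pairs, "range_mm"))
  if (!nrow(pairs_sub)) stop("invalid input: no pairs in subset/range",
                             call. = FALSE)
  wb <- window_bin_maps(w, pairs_sub, nw = nw, k = k)
  stim <- wb$obs[w$info$label == "stimulus", , drop = FALSE]
  base <- wb$obs[w$info$label == "baseline", , drop = FALSE]
  diff <- colMeans(stim) - colMeans(base)
  nf <- length(wb$freq)
  counts <- as.integer(table(factor(pairs_sub$bin_index, levels = wb$bins)))
  dm <- new_distance_map(matrix(diff, nf), "condition_difference",
                         wb$freq, wb$centers, counts)
  structure(list(diff_map = dm, stim = stim, base = base, freq = wb$freq,
                 centers = wb$centers),
            class = "condition_contrast")
}

#' Cluster-permutation significance mask for a condition contrast
#'
#' Permutes window condition labels; clusters are 4-connected components in
#' the frequency x distance-bin grid of supra-threshold t cells, and a
#' cluster is significant when its t mass exceeds the permutation null of
#' the maximum cluster mass (two-sided).
#'
#' @param contrast a `condition_contrast` from [condition_difference_map()].
#' @param n_perm permutations (default 1000).
#' @param alpha cluster significance level (default 0.05).
#' @param alpha_cell cluster-forming cell alpha (default 0.05).
#' @param seed RNG seed.
#' @return The contrast with added `sig_mask` (`distance_map` of 0/1),
#'   `clusters` data frame, and `perm` (raw engine output).
#' @export
cluster_permutation_map <- function(contrast, n_perm = 1000L, alpha = 0.05,
                                    alpha_cell = 0.05, seed = 1L) {
  nf <- length(contrast$freq); nb <- length(contrast$centers)
  res <- cluster_perm_test(contrast$stim, contrast$base, adjacency = "grid",
                           dims = c(nf, nb), n_perm = n_perm,
                           alpha_cell = alpha_cell, alpha = alpha, seed = seed)
  contrast$sig_mask <- new_distance_map(matrix(as.numeric(res$sig_mask), nf),
                                        "significance_mask", contrast$freq,
                                        contrast$centers,
                                        contrast$diff_map$n_pairs_per_bin)
  contrast$clusters <- res$clusters
  contrast$perm <- res
  contrast
}

#' High-gamma (50-200 Hz) summary curve of a contrast
#'
#' Per distance bin, the mean of the stimulus-minus-baseline difference map
#' over the 50-200 Hz rows: the classic high-gamma metric as a function of
#' bipolar distance.
#'
#' @param contrast a `condition_contrast` (needs `diff_map` covering
#'   50-200 Hz).
#' @param f_low,f_high band limits (default 50-200).
#' @return Named numeric vector (names = bin centers, mm).
#' @export
high_gamma_metric <- function(contrast, f_low = 50, f_high = 200) {
  dm <- contrast$diff_map
  sel <- dm$freq >= f_low & dm$freq <= f_high
  if (!any(sel)) stop("diff map does not cover the requested band",
                      call. = FALSE)
  out <- colMeans(dm$values[sel, , drop = FALSE])
  names(out) <- dm$bin_centers_mm
  out
}
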