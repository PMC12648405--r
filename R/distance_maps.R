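#' @keywords internal
new_distance_map <- function(values, stat, freq, bin_centers, n_pairs) {
  values <- as.matrix(values)
  stopifnot(nrow(values) == length(freq), ncol(values) == length(bin_centers))
  rownames(values) <- freq
  colnames(values) <- bin_centers
  structure(list(values = values, stat = stat, freq = freq,
                 bin_centers_mm = bin_centers, n_pairs_per_bin = n_pairs),
            class = "distance_map")
}

#' @export
print.distance_map <- function(x, ...) {
  cat(sprintf("<distance_map> stat=%s | %d freqs x %d bins (%g-%g mm), %d/%d bins populated\n",
              x$stat, length(x$freq), length(x$bin_centers_mm),
              min(x$bin_centers_mm), max(x$bin_centers_mm),
              sum(x$n_pairs_per_bin > 0), length(x$bin_centers_mm)))
  invisible(x)
}

map_bins <- function(pairs) {
  if (is.null(pairs$bin_index)) {
    stop("pairs must be binned first (bin_pairs_by_distance)", call. = FALSE)
  }
  w <- attr(pairs, "bin_width_mm"); rng <- attr(pairs, "range_mm")
  all_bins <- 0:floor((rng[2] - rng[1]) / w)
  list(bins = all_bins, centers = rng[1] + w * (all_bins + 0.5))
}

bin_mean <- function(values_by_pair, bin_index, all_bins, min_pairs) {
  # values_by_pair: freq x pair; returns freq x bin means + counts
  counts <- integer(length(all_bins))
  out <- matrix(NA_real_, nrow(values_by_pair), length(all_bins))
  for (j in seq_along(all_bins)) {
    sel <- which(bin_index == all_bins[j])
    counts[j] <- length(sel)
    if (length(sel) >= min_pairs) {
      out[, j] <- rowMeans(values_by_pair[, sel, drop = FALSE])
    }
  }
  list(means = out, counts = counts)
}

#' Distance-frequency map of z-scored square-root power
#'
#' Per distance bin, the mean across contributing pairs of square-root
#' power (already averaged over windows); then each frequency row is
#' z-scored across the populated bins (mean 0, population SD 1), exposing
#' the distance dependence at every frequency. Bins with too few pairs are
#' missing (`NA`), never zero.
#'
#' @param bipolar_spectra `bprr_spectra` of the bipolar pairs
#'   (linear power scale), rows aligned with `pairs`.
#' @param pairs binned `bipolar_pairs`.
#' @param min_pairs minimum pairs for a bin to be reported (default 5).
#' @return A `distance_map` (stat `"zscored_sqrt_power"`).
#' @export
sqrt_zscore_map <- function(bipolar_spectra, pairs, min_pairs = 5L) {
  stopifnot(nrow(bipolar_spectra$power) == nrow(pairs))
  mb <- map_bins(pairs)
  bm <- bin_mean(t(sqrt(bipolar_spectra$power)), pairs$bin_index, mb$bins,
                 min_pairs)
  filled <- colSums(!is.na(bm$means)) > 0
  if (sum(filled) < 2) {
    stop("invalid map: need at least 2 populated bins to z-score",
         call. = FALSE)
  }
  z <- t(apply(bm$means, 1L, function(row) {
    ok <- !is.na(row)
    mu <- mean(row[ok])
    sd_pop <- sqrt(mean((row[ok] - mu)^2))
    if (sd_pop == 0) row - mu else (row - mu) / sd_pop
  }))
  new_distance_map(z, "zscored_sqrt_power", bipolar_spectra$freq,
                   mb$centers, bm$counts)
}

#' Percent change of bipolar power relative to the referential mean
#'
#' For each pair, `100 * (P_bip - P_ref) / P_ref` at every frequency,
#' where `P_ref` is the arithmetic mean of the two contributing electrodes'
#' referential curves; per-pair percent changes are then averaged within
#' distance bins. Positive values mean the bipolar derivation carries more
#' power than the referential average (common-mode cancellation drives
#' values to -100%; subtracting two independent equal-power signals doubles
#' variance, +100%).
#'
#' @param bipolar_spectra `bprr_spectra` of pairs (linear scale), rows
#'   aligned with `pairs`.
#' @param referential_spectra `bprr_spectra` of the referential channels
#'   (linear scale), series ids matching contact ids.
#' @param pairs binned `bipolar_pairs`.
#' @param scale `"linear"` (default) compares power; `"sqrt"` compares
#'   square-root (amplitude-like) curves.
#' @param min_pairs minimum pairs per reported bin (default 5).
#' @param legacy_sign reproduce the opposite sign convention
#'   `100 * (ref - bip) / bip` (default FALSE).
#' @return A `distance_map` (stat `"percent_change"`).
#' @export
percent_change_map <- function(bipolar_spectra, referential_spectra, pairs,
                               scale = c("linear", "sqrt"), min_pairs = 5L,
                               legacy_sign = FALSE) {
  scale <- match.arg(scale)
  stopifnot(nrow(bipolar_spectra$power) == nrow(pairs),
            identical(bipolar_spectra$freq, referential_spectra$freq))
  a <- match(pairs$anode_id, referential_spectra$series_ids)
  c_ <- match(pairs$cathode_id, referential_spectra$series_ids)
  if (anyNA(a) || anyNA(c_)) {
    stop("montage error: pair electrode missing from referential spectra",
         call. = FALSE)
  }
  tf <- if (scale == "sqrt") sqrt else identity
  pb <- tf(bipolar_spectra$power)
  pr <- (tf(referential_spectra$power[a, , drop = FALSE]) +
         tf(referential_spectra$power[c_, , drop = FALSE])) / 2
  zero <- pr <= 0
  if (any(zero)) {
    warning(sprintf("%d cells with zero referential power excluded", sum(zero)))
    pr[zero] <- NA_real_
  }
  pc <- if (legacy_sign) 100 * (pr - pb) / pb else 100 * (pb - pr) / pr
  mb <- map_bins(pairs)
  bm <- bin_mean(t(pc), pairs$bin_index, mb$bins, min_pairs)
  new_distance_map(bm$means, "percent_change", bipolar_spectra$freq,
                   mb$centers, bm$counts)
}

#' Average distance maps with equal weight per subject
#'
#' @param maps list of `distance_map`s on identical grids.
#' @return A `distance_map`; cells are means over the maps in which they are
#'   defined, `n_pairs_per_bin` is summed.
#' @export
average_distance_maps <- function(maps) {
  stopifnot(length(maps) >= 1)
  vals <- lapply(maps, function(m) m$values)
  arr <- simplify2array(vals)
  avg <- apply(arr, c(1, 2), function(v) if (all(is.na(v))) NA_real_
               else mean(v, na.rm = TRUE))
  n <- Reduce(`+`, lapply(maps, function(m) m$n_pairs_per_bin))
  new_distance_map(avg, maps[[1]]$stat, maps[[1]]$freq,
                   maps[[1]]$bin_centers_mm, n)
}

#' Band-level comparison of bipolar vs referential power across subjects
#'
#' For each canonical band and each linear-ordinal distance, a paired
#' Wilcoxon signed-rank test across subjects of the subject-level band-mean
#' bipolar power against the subject's referential band-mean, with BH-FDR
#' across all band-by-distance tests. With a single subject only
#' descriptives are returned (statistics suppressed).
#'
#' @param subject_data list over subjects; each element a list with
#'   `referential` (a linear-scale `bprr_spectra` of that subject's
#'   electrodes) and `bipolar` (named list of linear-scale `bprr_spectra`,
#'   one per ordinal distance, names = distance in mm).
#' @param bands band definition table (default [band_table()]).
#' @param q FDR level (default 0.05).
#' @return Data frame: `band`, `distance_mm`, `n_subjects`,
#'   `median_diff` (median over subjects of bipolar - referential band
#'   mean), `iqr`, `effect_size` (matched rank-biserial correlation), `p`,
#'   `p_fdr`, `significant`.
#' @export
band_summary_tests <- function(subject_data, bands = band_table(), q = 0.05) {
  dists <- sort(unique(as.numeric(unlist(lapply(subject_data, function(s)
    names(s$bipolar))))))
  rows <- list()
  for (b in seq_len(nrow(bands))) {
    for (d in dists) {
      diffs <- vapply(subject_data, function(s) {
        key <- as.character(d)
        if (is.null(s$bipolar[[key]])) return(NA_real_)
        mean(band_mean_power(s$bipolar[[key]], bands$f_low[b], bands$f_high[b])) -
          mean(band_mean_power(s$referential, bands$f_low[b], bands$f_high[b]))
      }, 0)
      diffs <- diffs[!is.na(diffs)]
      n <- length(diffs)
      if (n >= 2 && any(diffs != 0)) {
        wt <- suppressWarnings(stats::wilcox.test(diffs, exact = TRUE))
        p <- wt$p.value
        es <- rank_biserial(diffs)
      } else if (n >= 2) {
        p <- 1; es <- 0
      } else {
        p <- NA_real_; es <- NA_real_
      }
      rows[[length(rows) + 1L]] <- data.frame(
        band = bands$band[b], distance_mm = d, n_subjects = n,
        median_diff = if (n) stats::median(diffs) else NA_real_,
        iqr = if (n) stats::IQR(diffs) else NA_real_,
        effect_size = es, p = p, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (all(is.na(out$p))) {
    out$p_fdr <- NA_real_; out$significant <- NA
  } else {
    fdr <- bh_fdr(out$p[!is.na(out$p)], q)
    out$p_fdr <- NA_real_; out$significant <- NA
    out$p_fdr[!is.na(out$p)] <- fdr$p_adjusted
    out$significant[!is.na(out$p)] <- fdr$reject
  }
  out
}

# matched-pairs rank-biserial correlation of differences vs zero
rank_biserial <- function(diffs) {
  diffs <- diffs[diffs != 0]
  if (!length(diffs)) return(0)
  r <- rank(abs(diffs))
  (sum(r[diffs > 0]) - sum(r[diffs < 0])) / sum(r)
}

#' Write / read a distance-frequency map as TSV
#'
#' Header row of bin centers, first column of frequencies, missing cells as
#' `NA`. A companion `<path>.npairs.tsv` stores pair counts per bin.
#'
#' @param map a `distance_map`.
#' @param path TSV path.
#' @export
write_map_tsv <- function(map, path) {
  df <- data.frame(frequency_hz = map$freq, map$values, check.names = FALSE)
  names(df)[-1] <- format(map$bin_centers_mm, trim = TRUE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  np <- data.frame(bin_center_mm = map$bin_centers_mm,
                   n_pairs = map$n_pairs_per_bin)
  utils::write.table(np, paste0(sub("\\.tsv$", "", path), ".npairs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_map_tsv
#' @param stat stat label to attach on read.
#' @export
read_map_tsv <- function(path, stat = "unknown") {
  df <- utils::read.delim(path, check.names = FALSE)
  freq <- df[[1]]
  vals <- as.matrix(df[, -1, drop = FALSE])
  centers <- as.numeric(colnames(vals))
  npath <- paste0(sub("\\.tsv$", "", path), ".npairs.tsv")
  n <- if (file.exists(npath)) utils::read.delim(npath)$n_pairs
       else rep(NA_integer_, length(centers))
  new_distance_map(vals, stat, freq, centers, n)
}

#' Heat-map plot of a distance-frequency map
#' @param x a `distance_map`.
#' @param ... passed to [graphics::image()].
#' @export
plot.distance_map <- function(x, ...) {
  graphics::image(x = x$bin_centers_mm, y = x$freq, z = t(x$values),
                  xlab = "bipolar distance (mm)", ylab = "frequency (Hz)",
                  main = x$stat, ...)
  invisible(x)
}
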