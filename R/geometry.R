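#' Electrode array constructor
#'
#' An electrode array describes the implanted contacts: label, 3D position in
#' millimetres, which physical component (grid / depth probe / strip) each
#' contact belongs to, the manufactured inter-contact pitch of that component,
#' a row label for grid contacts (contacts are ordered within a row), and a
#' bad-channel flag. Contacts flagged bad are excluded from every pair
#' enumeration.
#'
#' @param contact_id character vector of unique contact labels.
#' @param position numeric matrix (n x 3) of x/y/z coordinates in mm.
#' @param component_id character vector naming the physical component.
#' @param component_type one of `"grid"`, `"depth"`, `"strip"` per contact.
#' @param pitch_mm manufactured inter-electrode spacing in mm (per contact,
#'   constant within a component).
#' @param row_id row label for grid contacts (`NA` for depth/strip).
#' @param bad logical bad-channel flag.
#' @param subset logical flag marking a region-of-interest subset (e.g. the
#'   superior temporal gyrus contacts used in the task contrast); optional.
#' @return A data frame of class `electrode_array` with columns `contact_id`,
#'   `x_mm`, `y_mm`, `z_mm`, `component_id`, `component_type`, `pitch_mm`,
#'   `row_id`, `bad`, `subset`.
#' @export
electrode_array <- function(contact_id, position, component_id, component_type,
                            pitch_mm, row_id = NA_character_, bad = FALSE,
                            subset = FALSE) {
  position <- as.matrix(position)
  n <- length(contact_id)
  stopifnot(nrow(position) == n, ncol(position) == 3)
  arr <- data.frame(
    contact_id = as.character(contact_id),
    x_mm = as.numeric(position[, 1]),
    y_mm = as.numeric(position[, 2]),
    z_mm = as.numeric(position[, 3]),
    component_id = rep_len(as.character(component_id), n),
    component_type = rep_len(as.character(component_type), n),
    pitch_mm = rep_len(as.numeric(pitch_mm), n),
    row_id = rep_len(as.character(row_id), n),
    bad = rep_len(as.logical(bad), n),
    subset = rep_len(as.logical(subset), n),
    stringsAsFactors = FALSE
  )
  class(arr) <- c("electrode_array", "data.frame")
  validate_electrode_array(arr)
  arr
}

validate_electrode_array <- function(arr) {
  pos <- as.matrix(arr[, c("x_mm", "y_mm", "z_mm")])
  if (!all(is.finite(pos))) {
    stop("invalid geometry: electrode positions must be finite", call. = FALSE)
  }
  if (any(!is.finite(arr$pitch_mm)) || any(arr$pitch_mm <= 0)) {
    stop("invalid geometry: pitch_mm must be > 0", call. = FALSE)
  }
  if (anyDuplicated(arr$contact_id)) {
    stop("invalid geometry: duplicate contact_id", call. = FALSE)
  }
  grid <- arr$component_type == "grid"
  if (any(grid & (is.na(arr$row_id) | arr$row_id == ""))) {
    stop("invalid geometry: every grid contact needs a row_id", call. = FALSE)
  }
  bad_type <- !arr$component_type %in% c("grid", "depth", "strip")
  if (any(bad_type)) {
    stop("invalid geometry: component_type must be grid/depth/strip",
         call. = FALSE)
  }
  invisible(arr)
}

positions <- function(arr) as.matrix(arr[, c("x_mm", "y_mm", "z_mm")])

#' Euclidean distance between two 3D points (mm)
#'
#' @param a,b numeric length-3 coordinate vectors in mm.
#' @return Non-negative distance in mm.
#' @export
euclidean_distance <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != 3 || length(b) != 3 || !all(is.finite(c(a, b)))) {
    stop("invalid geometry: coordinates must be finite length-3 vectors",
         call. = FALSE)
  }
  sqrt(sum((a - b)^2))
}

new_bipolar_pairs <- function(df, scheme, bin_width_mm = NA_real_,
                              range_mm = c(NA_real_, NA_real_)) {
  rownames(df) <- NULL
  structure(df,
            scheme = scheme,
            bin_width_mm = bin_width_mm,
            range_mm = range_mm,
            class = c("bipolar_pairs", "data.frame"))
}

usable_contacts <- function(arr) which(!arr$bad)

# lines of contacts along which ordinal pairs are formed: each grid row is a
# line; each depth/strip component is one line. Contacts keep table order.
component_lines <- function(arr) {
  key <- ifelse(arr$component_type == "grid",
                paste0(arr$component_id, "\r", arr$row_id),
                arr$component_id)
  idx <- seq_len(nrow(arr))
  split(idx, factor(key, levels = unique(key)))
}

#' Enumerate linear-ordinal bipolar pairs
#'
#' Clinical-style bipolar pairs along the linear orientation of each
#' component: for depth probes and strips the whole contact line, for grids
#' each row independently. For skip `s` the pair (i, i+s) is formed with
#' non-Euclidean distance `s * pitch`. Bad contacts are excluded; a pair is
#' only formed between two usable contacts at exactly `s` positions apart in
#' the manufactured layout.
#'
#' @param arr an [electrode_array()].
#' @param max_skip largest ordinal skip (>= 1). Default 5, i.e. distances up
#'   to five times the manufactured pitch.
#' @return A `bipolar_pairs` data frame with columns `anode`, `cathode`
#'   (row indices into `arr`), `anode_id`, `cathode_id`, `component_id`,
#'   `distance_mm`, `ordinal_skip`.
#' @export
enumerate_linear_ordinal_pairs <- function(arr, max_skip = 5L) {
  stopifnot(inherits(arr, "electrode_array"))
  max_skip <- as.integer(max_skip)
  if (is.na(max_skip) || max_skip < 1L) {
    stop("invalid config: max_skip must be >= 1", call. = FALSE)
  }
  out <- list()
  for (line in component_lines(arr)) {
    n <- length(line)
    if (n < 2) next
    pitch <- arr$pitch_mm[line[1]]
    for (s in seq_len(min(max_skip, n - 1L))) {
      i <- seq_len(n - s)
      a <- line[i]; c_ <- line[i + s]
      keep <- !arr$bad[a] & !arr$bad[c_]
      if (!any(keep)) next
      out[[length(out) + 1L]] <- data.frame(
        anode = a[keep], cathode = c_[keep],
        component_id = arr$component_id[a[keep]],
        distance_mm = s * pitch,
        ordinal_skip = s,
        stringsAsFactors = FALSE
      )
    }
  }
  df <- if (length(out)) do.call(rbind, out) else
    data.frame(anode = integer(), cathode = integer(),
               component_id = character(), distance_mm = numeric(),
               ordinal_skip = integer(), stringsAsFactors = FALSE)
  df$anode_id <- arr$contact_id[df$anode]
  df$cathode_id <- arr$contact_id[df$cathode]
  new_bipolar_pairs(df, scheme = "ordinal")
}

#' Enumerate omnidirectional bipolar pairs
#'
#' Every unordered pair of usable contacts within the same component, with
#' its 3D Euclidean distance. Pairs are never formed across components.
#' The pair is canonically ordered with the lower row index as anode so the
#' derived signal's sign is deterministic.
#'
#' @param arr an [electrode_array()].
#' @return A `bipolar_pairs` data frame (scheme `"euclidean"`).
#' @export
enumerate_omnidirectional_pairs <- function(arr) {
  stopifnot(inherits(arr, "electrode_array"))
  pos <- positions(arr)
  out <- list()
  for (comp in unique(arr$component_id)) {
    idx <- which(arr$component_id == comp & !arr$bad)
    n <- length(idx)
    if (n < 2) next
    cmb <- utils::combn(idx, 2L)
    a <- cmb[1L, ]; c_ <- cmb[2L, ]
    d <- sqrt(rowSums((pos[a, , drop = FALSE] - pos[c_, , drop = FALSE])^2))
    out[[length(out) + 1L]] <- data.frame(
      anode = a, cathode = c_, component_id = comp,
      distance_mm = d, ordinal_skip = NA_integer_,
      stringsAsFactors = FALSE
    )
  }
  df <- if (length(out)) do.call(rbind, out) else
    data.frame(anode = integer(), cathode = integer(),
               component_id = character(), distance_mm = numeric(),
               ordinal_skip = integer(), stringsAsFactors = FALSE)
  df$anode_id <- arr$contact_id[df$anode]
  df$cathode_id <- arr$contact_id[df$cathode]
  new_bipolar_pairs(df, scheme = "euclidean")
}

#' Bin bipolar pairs by distance
#'
#' Pairs outside `range_mm` are dropped; the rest receive a half-open bin
#' `bin_index = floor((distance - range_mm[1]) / bin_width)`, i.e. bin edges
#' `[low, low + w)`. Bin 0 starts at the lower range edge.
#'
#' @param pairs a `bipolar_pairs` data frame.
#' @param bin_width bin width in mm (default 2).
#' @param range_mm closed distance interval retained (default `c(2, 60)`).
#' @return The filtered `bipolar_pairs` with a `bin_index` column and
#'   binning metadata attributes.
#' @export
bin_pairs_by_distance <- function(pairs, bin_width = 2, range_mm = c(2, 60)) {
  stopifnot(inherits(pairs, "bipolar_pairs"))
  if (!is.finite(bin_width) || bin_width <= 0) {
    stop("invalid config: bin_width must be > 0", call. = FALSE)
  }
  if (range_mm[2] < range_mm[1]) {
    stop("invalid config: inverted distance range", call. = FALSE)
  }
  keep <- pairs$distance_mm >= range_mm[1] & pairs$distance_mm <= range_mm[2]
  df <- as.data.frame(pairs)[keep, , drop = FALSE]
  df$bin_index <- as.integer(floor((df$distance_mm - range_mm[1]) / bin_width))
  new_bipolar_pairs(df, scheme = attr(pairs, "scheme"),
                    bin_width_mm = bin_width, range_mm = range_mm)
}

#' Bin centers of a binned pair set
#' @param pairs binned `bipolar_pairs`.
#' @param bins integer bin indices; defaults to all bins spanning the range.
#' @return numeric vector of bin-center distances (mm).
#' @export
pair_bin_centers <- function(pairs, bins = NULL) {
  w <- attr(pairs, "bin_width_mm")
  lo <- attr(pairs, "range_mm")[1]
  if (is.null(bins)) {
    hi <- attr(pairs, "range_mm")[2]
    bins <- 0:floor((hi - lo) / w)
  }
  lo + w * (bins + 0.5)
}

#' Randomly subsample pairs within each distance bin
#'
#' Caps the number of pairs per bin (omnidirectional sets on large grids
#' contain tens of thousands of pairs; the binned averages converge with a
#' few hundred per bin).
#'
#' @param pairs binned `bipolar_pairs`.
#' @param max_per_bin maximum retained pairs per bin.
#' @param seed RNG seed for reproducible subsampling.
#' @return The subsampled `bipolar_pairs`.
#' @export
subsample_pairs <- function(pairs, max_per_bin = 250L, seed = 1L) {
  stopifnot(!is.null(pairs$bin_index))
  keep <- with_local_seed(seed, {
    unlist(lapply(split(seq_len(nrow(pairs)), pairs$bin_index), function(i) {
      if (length(i) <= max_per_bin) i else sample(i, max_per_bin)
    }), use.names = FALSE)
  })
  df <- as.data.frame(pairs)[sort(keep), , drop = FALSE]
  new_bipolar_pairs(df, scheme = attr(pairs, "scheme"),
                    bin_width_mm = attr(pairs, "bin_width_mm"),
                    range_mm = attr(pairs, "range_mm"))
}

#' Apply a bipolar montage to a recording or window set
#'
#' Forms one derived channel per pair as the sample-wise difference
#' anode minus cathode. Sample counts are unchanged; any component common to
#' both contacts (shared reference, line noise) cancels exactly.
#'
#' @param x an `ieeg_recording` or `ieeg_windows` object.
#' @param pairs a `bipolar_pairs` data frame whose indices refer to channels
#'   of `x` (matched by contact label when channel ids are present).
#' @return Object of the same class with one channel per pair, channel ids
#'   `"anode-cathode"`.
#' @export
apply_bipolar <- function(x, pairs) UseMethod("apply_bipolar")

pair_channel_index <- function(pairs, channel_ids) {
  a <- match(pairs$anode_id, channel_ids)
  c_ <- match(pairs$cathode_id, channel_ids)
  missing <- which(is.na(a) | is.na(c_))
  if (length(missing)) {
    stop(sprintf("montage error: pair %s-%s refers to unrecorded channel",
                 pairs$anode_id[missing[1]], pairs$cathode_id[missing[1]]),
         call. = FALSE)
  }
  list(a = a, c = c_)
}

#' @export
apply_bipolar.ieeg_recording <- function(x, pairs) {
  ix <- pair_channel_index(pairs, x$channel_ids)
  out <- x$samples[ix$a, , drop = FALSE] - x$samples[ix$c, , drop = FALSE]
  new_recording(out, x$fs, paste0(pairs$anode_id, "-", pairs$cathode_id))
}

#' @export
apply_bipolar.ieeg_windows <- function(x, pairs) {
  ix <- pair_channel_index(pairs, x$channel_ids)
  d <- x$data[ix$a, , , drop = FALSE] - x$data[ix$c, , , drop = FALSE]
  new_windows(d, x$fs, paste0(pairs$anode_id, "-", pairs$cathode_id), x$info)
}

#' Read / write an electrode table
#'
#' TSV with columns `contact_id, x_mm, y_mm, z_mm, component_id,
#' component_type, pitch_mm, row_id, bad` (0/1) and optionally `subset`.
#'
#' @param path file path.
#' @return [electrode_array()] for the reader; invisibly `path` for the
#'   writer.
#' @export
read_electrode_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(contact_id = "character"))
  if (is.null(df$subset)) df$subset <- 0L
  if (is.null(df$row_id)) df$row_id <- NA_character_
  electrode_array(df$contact_id, cbind(df$x_mm, df$y_mm, df$z_mm),
                  df$component_id, df$component_type, df$pitch_mm,
                  as.character(df$row_id), as.logical(df$bad),
                  as.logical(df$subset))
}

#' @rdname read_electrode_table
#' @param arr electrode array to write.
#' @export
write_electrode_table <- function(arr, path) {
  out <- as.data.frame(arr)
  out$bad <- as.integer(out$bad)
  out$subset <- as.integer(out$subset)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a pair set as TSV
#'
#' Columns: `anode, cathode, distance_mm, scheme, ordinal_skip, bin_index`.
#' @param pairs `bipolar_pairs`.
#' @param path file path.
#' @export
write_pair_table <- function(pairs, path) {
  out <- data.frame(anode = pairs$anode_id, cathode = pairs$cathode_id,
                    distance_mm = pairs$distance_mm,
                    scheme = attr(pairs, "scheme"),
                    ordinal_skip = pairs$ordinal_skip,
                    bin_index = if (is.null(pairs$bin_index)) NA_integer_
                                else pairs$bin_index)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
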