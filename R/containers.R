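#' @keywords internal
new_recording <- function(samples, fs, channel_ids) {
  samples <- as.matrix(samples)
  stopifnot(is.numeric(fs), fs > 0, nrow(samples) == length(channel_ids))
  structure(list(samples = samples, fs = fs,
                 channel_ids = as.character(channel_ids)),
            class = "ieeg_recording")
}

#' Construct an intracranial recording object
#'
#' @param samples numeric channel-by-time matrix (microvolts).
#' @param fs sampling rate in Hz.
#' @param channel_ids channel labels matching the electrode table.
#' @return An `ieeg_recording` (list with `samples`, `fs`, `channel_ids`).
#' @export
ieeg_recording <- function(samples, fs, channel_ids = NULL) {
  if (is.null(channel_ids)) {
    channel_ids <- rownames(samples)
    if (is.null(channel_ids)) channel_ids <- paste0("ch", seq_len(nrow(samples)))
  }
  new_recording(samples, fs, channel_ids)
}

#' @export
print.ieeg_recording <- function(x, ...) {
  cat(sprintf("<ieeg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$samples), ncol(x$samples), x$fs,
              ncol(x$samples) / x$fs))
  invisible(x)
}

rec_duration <- function(rec) ncol(rec$samples) / rec$fs

#' @keywords internal
new_windows <- function(data, fs, channel_ids, info) {
  stopifnot(length(dim(data)) == 3)
  structure(list(data = data, fs = fs, channel_ids = as.character(channel_ids),
                 info = info),
            class = "ieeg_windows")
}

#' Construct a window set
#'
#' One-second signal windows with labels. `data` is a 3D array
#' channel x sample x window; `info` carries one row per window with
#' `start_sample` (1-based, into the source recording) and
#' `label` (`"baseline"`, `"ied"`, or `"stimulus"`).
#'
#' @param data channel x sample x window numeric array.
#' @param fs sampling rate (Hz); windows are `fs` samples (1 s).
#' @param channel_ids channel labels.
#' @param info data frame with columns `start_sample`, `label`.
#' @return An `ieeg_windows` object.
#' @export
ieeg_windows <- function(data, fs, channel_ids = NULL, info = NULL) {
  if (is.null(channel_ids)) channel_ids <- paste0("ch", seq_len(dim(data)[1]))
  if (is.null(info)) {
    info <- data.frame(start_sample = rep(NA_integer_, dim(data)[3]),
                       label = "baseline")
  }
  stopifnot(nrow(info) == dim(data)[3])
  new_windows(data, fs, channel_ids, info)
}

#' @export
print.ieeg_windows <- function(x, ...) {
  cat(sprintf("<ieeg_windows> %d windows (%s) | %d channels x %d samples @ %g Hz\n",
              dim(x$data)[3],
              paste(sprintf("%s:%d", names(table(x$info$label)),
                            as.integer(table(x$info$label))), collapse = ", "),
              dim(x$data)[1], dim(x$data)[2], x$fs))
  invisible(x)
}

n_windows <- function(w) dim(w$data)[3]

#' Subset a window set by label or index
#' @param w `ieeg_windows`.
#' @param label keep windows with this label (optional).
#' @param index integer window indices (optional).
#' @return `ieeg_windows`.
#' @export
select_windows <- function(w, label = NULL, index = NULL) {
  keep <- seq_len(n_windows(w))
  if (!is.null(label)) keep <- keep[w$info$label[keep] %in% label]
  if (!is.null(index)) keep <- intersect(keep, index)
  new_windows(w$data[, , keep, drop = FALSE], w$fs, w$channel_ids,
              w$info[keep, , drop = FALSE])
}

# Run code with a temporarily-seeded RNG, restoring global RNG state.
with_local_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

# derive a child seed (kept below 2^31)
child_seed <- function(seed, k) (as.integer(seed) * 1009L + as.integer(k)) %% 2147483629L
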