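# Cluster-based permutation testing, shared by the task contrast
# (frequency x distance grids, 4-connected adjacency) and the IED analysis
# (time series, chain adjacency).

# connected components of supra-threshold cells.
# mask: logical vector; for adjacency "grid", dims = c(nr, nc), neighbours
# are up/down/left/right; for "linear", neighbours are adjacent indices.
label_clusters <- function(mask, adjacency = c("linear", "grid"), dims = NULL) {
  adjacency <- match.arg(adjacency)
  n <- length(mask)
  labels <- integer(n)
  if (!any(mask)) return(labels)
  if (adjacency == "linear") {
    idx <- which(mask)
    breaks <- c(TRUE, diff(idx) > 1L)
    labels[idx] <- cumsum(breaks)
    return(labels)
  }
  nr <- dims[1]; nc <- dims[2]
  stopifnot(nr * nc == n)
  lab <- 0L
  for (start in which(mask)) {
    if (labels[start] > 0L) next
    lab <- lab + 1L
    queue <- start
    labels[start] <- lab
    while (length(queue)) {
      cell <- queue[[1L]]; queue <- queue[-1L]
      r <- (cell - 1L) %% nr + 1L
      c_ <- (cell - 1L) %/% nr + 1L
      nb <- c(if (r > 1L) cell - 1L, if (r < nr) cell + 1L,
              if (c_ > 1L) cell - nr, if (c_ < nc) cell + nr)
      nb <- nb[mask[nb] & labels[nb] == 0L]
      labels[nb] <- lab
      queue <- c(queue, nb)
    }
  }
  labels
}

# pooled-variance two-sample t per cell. x: n1 x m, y: n2 x m.
cellwise_t <- function(x, y) {
  n1 <- nrow(x); n2 <- nrow(y)
  m1 <- colMeans(x); m2 <- colMeans(y)
  v1 <- colSums(x^2) - n1 * m1^2
  v2 <- colSums(y^2) - n2 * m2^2
  sp <- (v1 + v2) / (n1 + n2 - 2)
  se <- sqrt(sp * (1 / n1 + 1 / n2))
  se[se == 0] <- Inf
  (m1 - m2) / se
}

# signed cluster masses for a t-map: positive and negative clusters
# separately; returns list(labels, masses) where labels>0 positive, <0
# negative (offset), masses named by label.
signed_clusters <- function(tval, thr, adjacency, dims) {
  pos <- label_clusters(tval > thr, adjacency, dims)
  neg <- label_clusters(tval < -thr, adjacency, dims)
  masses_p <- if (max(pos) > 0)
    vapply(seq_len(max(pos)), function(l) sum(tval[pos == l]), 0) else numeric(0)
  masses_n <- if (max(neg) > 0)
    vapply(seq_len(max(neg)), function(l) sum(tval[neg == l]), 0) else numeric(0)
  list(pos = pos, neg = neg, masses_pos = masses_p, masses_neg = masses_n)
}

#' Two-sided cluster-based permutation test
#'
#' Compares two groups of observations over a grid of cells. Cells with a
#' pooled two-sample t beyond the two-sided `alpha_cell` quantile form
#' clusters (4-connected on a grid, contiguous runs on a line); each
#' cluster's mass is the sum of its t values, and significance is assessed
#' against the permutation distribution of the maximum absolute cluster
#' mass under shuffled group labels.
#'
#' @param x,y numeric observation matrices (rows = observations, columns =
#'   cells); same column count.
#' @param adjacency `"grid"` (4-neighbourhood, supply `dims`) or
#'   `"linear"` (chain over columns).
#' @param dims `c(n_rows, n_cols)` of the cell grid when
#'   `adjacency = "grid"`.
#' @param n_perm number of label permutations (default 1000, minimum 100).
#' @param alpha_cell cluster-forming cell-level alpha (two-sided t
#'   threshold; default 0.05).
#' @param alpha cluster-level significance threshold (default 0.05).
#' @param seed RNG seed; fixed seeds give bit-reproducible masks.
#' @param warn_min warn when either group has fewer observations
#'   (default 20).
#' @return List with elements `t` (observed t per cell), `sig_mask` (logical
#'   per cell), `clusters` (data frame: id, sign, mass, p, n_cells),
#'   `cluster_id` (per-cell signed cluster label, 0 = none), `null_max`
#'   (permutation null of max |mass|), `threshold` (cluster-forming t).
#' @export
cluster_perm_test <- function(x, y, adjacency = c("grid", "linear"),
                              dims = NULL, n_perm = 1000L, alpha_cell = 0.05,
                              alpha = 0.05, seed = 1L, warn_min = 20L) {
  adjacency <- match.arg(adjacency)
  x <- as.matrix(x); y <- as.matrix(y)
  stopifnot(ncol(x) == ncol(y))
  if (n_perm < 100L) stop("invalid config: n_perm must be >= 100",
                          call. = FALSE)
  if (min(nrow(x), nrow(y)) < warn_min) {
    warning(sprintf("fewer than %d observations in a condition (%d vs %d)",
                    warn_min, nrow(x), nrow(y)))
  }
  if (adjacency == "grid") stopifnot(!is.null(dims))
  n1 <- nrow(x); n <- n1 + nrow(y)
  thr <- stats::qt(1 - alpha_cell / 2, df = n - 2)
  all_obs <- rbind(x, y)
  tobs <- cellwise_t(x, y)
  cl <- signed_clusters(tobs, thr, adjacency, dims)
  null_max <- with_local_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      pick <- sample.int(n, n1)
      tp <- cellwise_t(all_obs[pick, , drop = FALSE],
                       all_obs[-pick, , drop = FALSE])
      clp <- signed_clusters(tp, thr, adjacency, dims)
      m <- c(clp$masses_pos, abs(clp$masses_neg))
      if (length(m)) max(m) else 0
    }, 0)
  })
  ids <- integer(0); sign_ <- integer(0); mass <- numeric(0); ncell <- integer(0)
  cluster_id <- integer(length(tobs))
  k <- 0L
  for (l in seq_along(cl$masses_pos)) {
    k <- k + 1L; ids <- c(ids, k); sign_ <- c(sign_, 1L)
    mass <- c(mass, cl$masses_pos[l]); ncell <- c(ncell, sum(cl$pos == l))
    cluster_id[cl$pos == l] <- k
  }
  for (l in seq_along(cl$masses_neg)) {
    k <- k + 1L; ids <- c(ids, k); sign_ <- c(sign_, -1L)
    mass <- c(mass, cl$masses_neg[l]); ncell <- c(ncell, sum(cl$neg == l))
    cluster_id[cl$neg == l] <- -k
  }
  p <- vapply(mass, function(m) (1 + sum(null_max >= abs(m))) / (n_perm + 1), 0)
  clusters <- data.frame(id = ids, sign = sign_, mass = mass, p = p,
                         n_cells = ncell)
  sig <- rep(FALSE, length(tobs))
  for (i in seq_len(nrow(clusters))) {
    if (clusters$p[i] < alpha) sig[abs(cluster_id) == clusters$id[i]] <- TRUE
  }
  list(t = tobs, sig_mask = sig, clusters = clusters, cluster_id = cluster_id,
       null_max = null_max, threshold = thr)
}

#' Benjamini-Hochberg false discovery rate
#'
#' Standard step-up procedure (via [stats::p.adjust()]): adjusted p-values
#' are monotone in the raw-p ranks, and a hypothesis is rejected when its
#' adjusted p is at or below `q`.
#'
#' @param p vector of p-values in `[0, 1]`.
#' @param q FDR level (default 0.05).
#' @return List with `reject` (logical), `p_adjusted`.
#' @export
bh_fdr <- function(p, q = 0.05) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop("invalid input: p-values must lie in [0, 1]", call. = FALSE)
  }
  adj <- stats::p.adjust(p, method = "BH")
  list(reject = adj <= q, p_adjusted = adj)
}
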