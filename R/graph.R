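#' Binarize a connectivity matrix
#'
#' An edge is kept wherever the correlation strictly exceeds the threshold
#' (`r > threshold_r`); signed values are used as-is, so strong negative
#' correlations never become edges, and a value exactly at the threshold does
#' not either. The diagonal is forced to zero (no self-loops).
#'
#' @param fc a `pearson_r` [edge_matrix].
#' @param threshold_r correlation threshold (default 0.3, the operating point
#'   of the pipeline; see [threshold_sweep()]).
#' @return a `binary_adjacency`: binary symmetric matrix with attribute
#'   `threshold_r`.
#' @export
binarize <- function(fc, threshold_r = 0.3) {
  adj <- (unclass(fc) > threshold_r) * 1L
  diag(adj) <- 0L
  dimnames(adj) <- dimnames(fc)
  structure(adj, threshold_r = threshold_r,
            class = c("binary_adjacency", class(matrix())))
}

#' Node degrees and mean degree
#'
#' @param adj a binary adjacency matrix.
#' @return `node_degrees`: named integer vector of row sums;
#'   `mean_degree`: their mean.
#' @export
node_degrees <- function(adj) {
  stats::setNames(as.integer(rowSums(adj)), rownames(adj))
}

#' @rdname node_degrees
#' @export
mean_degree <- function(adj) {
  mean(rowSums(adj))
}

#' Clustering coefficients
#'
#' Local clustering `C_i = 2 T_i / (k_i (k_i - 1))` where `T_i` is the number
#' of edges among the neighbors of node `i` (i.e. triangles through `i`) and
#' `k_i` its degree; `C_i = 0` when `k_i < 2`, the convention of the standard
#' brain-connectivity toolboxes. The mean is taken over all nodes.
#'
#' @param adj a binary adjacency matrix.
#' @return list with per-node `coefficients` and their `mean`.
#' @export
clustering_coefficients <- function(adj) {
  a <- unclass(adj)
  k <- rowSums(a)
  triangles <- diag(a %*% a %*% a) / 2       # edges among neighbours
  ci <- ifelse(k >= 2, 2 * triangles / (k * (k - 1)), 0)
  list(coefficients = stats::setNames(ci, rownames(adj)), mean = mean(ci))
}

# all-pairs unweighted shortest-path lengths by breadth-first search
bfs_distances <- function(adj) {
  a <- unclass(adj) > 0
  n <- nrow(a)
  d <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    dist <- rep(Inf, n)
    dist[s] <- 0
    frontier <- s
    lev <- 0L
    while (length(frontier)) {
      lev <- lev + 1L
      nxt <- which(is.infinite(dist) &
                     (colSums(a[frontier, , drop = FALSE]) > 0))
      dist[nxt] <- lev
      frontier <- nxt
    }
    d[s, ] <- dist
  }
  d
}

#' Characteristic path length
#'
#' Mean unweighted shortest-path length over all ordered node pairs `i != j`
#' with a finite distance; the fraction of disconnected (infinite-distance)
#' pairs is reported alongside rather than folded into the mean. Alternatively
#' `method = "efficiency"` returns the harmonic-mean distance
#' (`1 / global efficiency`), which penalizes disconnection instead of
#' excluding it.
#'
#' @param adj a binary adjacency matrix.
#' @param method `"finite_mean"` (default) or `"efficiency"`.
#' @return list with `L` and `frac_disconnected_pairs`.
#' @export
characteristic_path_length <- function(adj,
                                       method = c("finite_mean", "efficiency")) {
  method <- match.arg(method)
  if (sum(adj) == 0) stop("graph has no edges; path length undefined")
  d <- bfs_distances(adj)
  off <- d[row(d) != col(d)]
  frac_inf <- mean(is.infinite(off))
  L <- if (method == "finite_mean") mean(off[is.finite(off)])
  else 1 / mean(1 / off)       # 1/efficiency; infinite distances contribute 0
  list(L = L, frac_disconnected_pairs = frac_inf)
}

#' All three network measures at one threshold
#'
#' @param fc a `pearson_r` [edge_matrix].
#' @param threshold_r binarization threshold.
#' @param subject_id carried into the record.
#' @return one-row data.frame: `subject_id`, `threshold_r`, `char_path_length`,
#'   `mean_clustering`, `mean_degree`, `frac_disconnected_pairs`.
#' @export
graph_metrics <- function(fc, threshold_r = 0.3, subject_id = NA_character_) {
  adj <- binarize(fc, threshold_r)
  pl <- if (sum(adj) > 0) characteristic_path_length(adj)
  else list(L = NA_real_, frac_disconnected_pairs = 1)
  data.frame(subject_id = subject_id, threshold_r = threshold_r,
             char_path_length = pl$L,
             mean_clustering = clustering_coefficients(adj)$mean,
             mean_degree = mean_degree(adj),
             frac_disconnected_pairs = pl$frac_disconnected_pairs)
}

#' Threshold sweep of the network measures
#'
#' Binarizes the FC matrix at every threshold of a grid (default 0.1 to 0.5 in
#' steps of 0.01, i.e. 41 thresholds) and computes the three network measures
#' plus the heavy-tail diagnostic at each.
#'
#' @param fc a `pearson_r` [edge_matrix].
#' @param r_min,r_max,step grid of thresholds.
#' @param subject_id carried into the records.
#' @return data.frame with one row per threshold; columns as in
#'   [graph_metrics()] plus `degree_tail_r2`.
#' @export
threshold_sweep <- function(fc, r_min = 0.1, r_max = 0.5, step = 0.01,
                            subject_id = NA_character_) {
  thresholds <- seq(r_min, r_max, by = step)
  rows <- lapply(thresholds, function(thr) {
    rec <- graph_metrics(fc, thr, subject_id)
    rec$degree_tail_r2 <- degree_distribution_diagnostic(binarize(fc, thr))
    rec
  })
  do.call(rbind, rows)
}

#' Heavy-tail (scale-freeness) diagnostic of the degree distribution
#'
#' Coefficient of determination of a straight-line fit to the log-log degree
#' survival function `S(d) = P(degree >= d)` over nodes with degree >= 1.
#' A value near 1 indicates the power-law-like decay expected of
#' scale-free-ish networks; regular or narrowly peaked degree distributions
#' score lower. This is a heuristic screening diagnostic, not a formal
#' power-law test.
#'
#' @param adj a binary adjacency matrix (>= 10 nodes of degree >= 1 for a
#'   meaningful fit).
#' @return the R-squared of the fit, or `NA` when fewer than 3 distinct
#'   positive degrees exist (e.g. a regular graph).
#' @export
degree_distribution_diagnostic <- function(adj) {
  k <- rowSums(adj)
  k <- k[k >= 1]
  if (length(k) < 10L) return(NA_real_)
  ds <- sort(unique(k))
  if (length(ds) < 3L) return(NA_real_)
  surv <- vapply(ds, function(d) mean(k >= d), numeric(1L))
  fit <- stats::lm(log(surv) ~ log(ds))
  # a perfect log-log fit is a valid (maximal) score, not a modelling problem
  suppressWarnings(summary(fit)$r.squared)
}
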