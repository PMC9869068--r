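#' Static Pearson functional connectivity
#'
#' Pearson correlation between every pair of ROI series over the entire
#' record, the classic static FC matrix.
#'
#' @param ts a [roi_ts].
#' @return an [edge_matrix] of kind `pearson_r` (diagonal exactly 1).
#' @examples
#' ts <- roi_ts(matrix(rnorm(300), 100, 3), tr = 3)
#' fc <- pearson_fc(ts)
#' @export
pearson_fc <- function(ts) {
  ts <- as_roi_ts(ts)
  sds <- apply(ts, 2L, stats::sd)
  if (any(sds == 0))
    stop("constant ROI series: ", paste(colnames(ts)[sds == 0], collapse = ", "))
  r <- stats::cor(unclass(ts))
  r[r > 1] <- 1; r[r < -1] <- -1
  diag(r) <- 1
  edge_matrix(r, "pearson_r", roi_labels = colnames(ts))
}

#' Global mean functional connectivity
#'
#' Mean of the strict upper triangle of a correlation matrix (diagonal
#' excluded) — the per-subject scalar used to ask whether group differences
#' are global or edge-specific.
#'
#' @param m an [edge_matrix] (any kind; typically `pearson_r`).
#' @return scalar mean over the `N (N - 1) / 2` edges.
#' @export
global_mean_fc <- function(m) {
  mean(m[upper.tri(m)])
}

#' Per-group mean and SD edge matrices
#'
#' Entry-wise mean and sample standard deviation of a set of subject-level
#' edge matrices, split by group.
#'
#' @param matrices named list of [edge_matrix] (names = subject ids), all of
#'   the same kind and edge indexing.
#' @param groups factor/character of group labels aligned with `matrices`.
#' @return list with one element per group level, each holding `mean` and `sd`
#'   matrices and `n`.
#' @export
group_mean_fc <- function(matrices, groups) {
  groups <- as.factor(groups)
  if (length(matrices) != length(groups))
    stop("matrices and groups lengths differ")
  if (any(table(groups) < 2L))
    stop("every group needs at least 2 subjects")
  out <- lapply(levels(groups), function(g) {
    ms <- matrices[groups == g]
    arr <- simplify2array(lapply(ms, unclass))
    list(mean = apply(arr, c(1L, 2L), mean),
         sd = apply(arr, c(1L, 2L), stats::sd),
         n = length(ms))
  })
  names(out) <- levels(groups)
  out
}

#' Robust outlier screen (three scaled MADs from the median)
#'
#' Flags values farther than `k` scaled median absolute deviations from the
#' median, the robust screen applied to per-subject edge values before
#' re-running group statistics. The MAD is scaled by the normal-consistency
#' constant 1.4826 so it estimates the SD for Gaussian data. When the MAD is
#' zero (degenerate sample) any value different from the median is flagged and
#' a warning is raised.
#'
#' @param values numeric vector of per-subject scalars (length >= 3).
#' @param k multiplier (default 3).
#' @return logical vector: `TRUE` where the value is an outlier.
#' @examples
#' mad_outliers(c(10, 12, 11, 30))  # flags the 30
#' @export
mad_outliers <- function(values, k = 3) {
  if (length(values) < 3L) stop("need at least 3 values for the MAD screen")
  med <- stats::median(values)
  m <- stats::mad(values)        # 1.4826-scaled by default
  if (m == 0) {
    warning("MAD is zero; flagging any value different from the median")
    return(values != med)
  }
  abs(values - med) > k * m
}
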