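#' Symmetric edge matrix
#'
#' `N x N` symmetric matrix holding one value per ROI pair. Three metric kinds
#' are used in the pipeline, each with its own diagonal convention:
#' \describe{
#'   \item{`pearson_r`}{Pearson correlation, entries in `[-1, 1]`, diagonal 1.}
#'   \item{`sd_across_windows`}{SD of an edge's correlation across sliding
#'     windows, entries `>= 0`, diagonal 0.}
#'   \item{`coactivation_count`}{number of timepoints at which both ROIs have a
#'     suprathreshold event; non-negative integers, diagonal = per-ROI event
#'     totals.}
#' }
#'
#' @param values numeric symmetric `N x N` matrix.
#' @param metric_kind one of `"pearson_r"`, `"sd_across_windows"`,
#'   `"coactivation_count"`.
#' @param roi_labels ROI labels in the canonical column order (defaults to the
#'   matrix dimnames).
#' @param tol symmetry tolerance.
#' @return an `edge_matrix` object.
#' @export
edge_matrix <- function(values,
                        metric_kind = c("pearson_r", "sd_across_windows",
                                        "coactivation_count"),
                        roi_labels = colnames(values), tol = 1e-8) {
  metric_kind <- match.arg(metric_kind)
  values <- as.matrix(values)
  n <- ncol(values)
  if (nrow(values) != n) stop("edge matrix must be square")
  if (is.null(roi_labels)) roi_labels <- sprintf("ROI%03d", seq_len(n))
  roi_labels <- as.character(roi_labels)
  if (length(roi_labels) != n || anyDuplicated(roi_labels))
    stop("roi_labels must be unique and match the matrix dimension")
  if (any(!is.finite(values))) stop("edge matrix contains non-finite values")
  if (max(abs(values - t(values))) > tol)
    stop("edge matrix is not symmetric within tolerance ", tol)
  values <- (values + t(values)) / 2
  d <- diag(values)
  off <- values[upper.tri(values)]
  switch(metric_kind,
    pearson_r = {
      if (any(abs(off) > 1 + tol)) stop("pearson_r entries must lie in [-1, 1]")
      if (any(abs(d - 1) > tol)) stop("pearson_r diagonal must be 1")
      diag(values) <- 1
    },
    sd_across_windows = {
      if (any(off < -tol)) stop("sd_across_windows entries must be >= 0")
      if (any(abs(d) > tol)) stop("sd_across_windows diagonal must be 0")
      diag(values) <- 0
    },
    coactivation_count = {
      if (any(values < 0) || any(abs(values - round(values)) > tol))
        stop("coactivation_count entries must be non-negative integers")
      values <- round(values)
      if (any(off > pmin(rep(d, each = n), rep(d, times = n))[upper.tri(values)]))
        stop("co-activation count exceeds a per-ROI event total")
    })
  dimnames(values) <- list(roi_labels, roi_labels)
  structure(values, metric_kind = metric_kind,
            class = c("edge_matrix", class(matrix())))
}

#' @export
print.edge_matrix <- function(x, ...) {
  cat(sprintf("%d x %d symmetric edge matrix (%s)\n",
              nrow(x), ncol(x), attr(x, "metric_kind")))
  up <- x[upper.tri(x)]
  cat(sprintf("  off-diagonal: min %.4g, median %.4g, max %.4g\n",
              min(up), stats::median(up), max(up)))
  invisible(x)
}

#' Vector of upper-triangle edge values
#'
#' Extract the strict upper triangle of an [edge_matrix] in column-major order,
#' named `"roi_i|roi_j"` with `i < j` under the canonical ROI ordering.
#'
#' @param m an [edge_matrix] (or plain symmetric matrix).
#' @return named numeric vector of length `N (N - 1) / 2`.
#' @export
edge_values <- function(m) {
  labels <- colnames(m)
  ut <- upper.tri(m)
  idx <- which(ut, arr.ind = TRUE)
  stats::setNames(m[ut], paste(labels[idx[, 1L]], labels[idx[, 2L]], sep = "|"))
}

# index table of the strict upper triangle (i < j), column-major
edge_index <- function(n, labels = NULL) {
  idx <- which(upper.tri(diag(n)), arr.ind = TRUE)
  out <- data.frame(i = idx[, 1L], j = idx[, 2L])
  if (!is.null(labels)) {
    out$roi_i <- labels[out$i]
    out$roi_j <- labels[out$j]
  }
  out
}
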