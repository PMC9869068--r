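#' Point-process event extraction
#'
#' Reduces a z-scored BOLD matrix to a binary event raster at the 1-sigma
#' threshold. Two event definitions are exposed:
#' \describe{
#'   \item{`"point"`}{(default) an event at `(t, i)` whenever
#'     `z_i(t) > threshold` — every suprathreshold sample counts, which is the
#'     definition the pairwise co-activation ("matrix of addition") sums over.}
#'   \item{`"upcrossing"`}{an event only where the series moves from at-or-
#'     below to strictly above the threshold (the first sample counts if it is
#'     already above) — the definition under which BOLD series show on the
#'     order of 8.5 crossings per 420 s scan.}
#' }
#' The threshold is strict (`>`, not `>=`); on continuous data the difference
#' has measure zero. Input must already be z-scored (see [zscore()]) so that
#' 1 sigma is exactly 1.0; a column whose SD deviates from 1 by more than
#' `1e-6` raises an error.
#'
#' @param zts a z-scored [roi_ts].
#' @param threshold_sigma threshold in SD units (default 1).
#' @param mode `"point"` or `"upcrossing"`.
#' @return an `event_raster`: binary `T x N` matrix with attributes
#'   `threshold_sigma` and `mode`.
#' @export
point_events <- function(zts, threshold_sigma = 1,
                         mode = c("point", "upcrossing")) {
  mode <- match.arg(mode)
  zts <- as_roi_ts(zts)
  sds <- apply(zts, 2L, stats::sd)
  off <- which(abs(sds - 1) > 1e-6)
  if (length(off))
    stop("input does not look z-scored (column SD differs from 1): ",
         paste(colnames(zts)[off], collapse = ", "),
         "; run zscore() first")
  above <- unclass(zts) > threshold_sigma
  ev <- if (mode == "point") above
  else rbind(above[1L, , drop = FALSE],
             above[-1L, , drop = FALSE] & !above[-nrow(above), , drop = FALSE])
  storage.mode(ev) <- "integer"
  dimnames(ev) <- list(NULL, colnames(zts))
  structure(ev, threshold_sigma = threshold_sigma, mode = mode,
            class = c("event_raster", class(matrix())))
}

#' @export
print.event_raster <- function(x, ...) {
  cat(sprintf("Event raster: %d timepoints x %d ROIs (threshold %g sigma, mode '%s')\n",
              nrow(x), ncol(x), attr(x, "threshold_sigma"), attr(x, "mode")))
  cat(sprintf("  events per ROI: median %g, range %d-%d\n",
              stats::median(colSums(x)), min(colSums(x)), max(colSums(x))))
  invisible(x)
}

#' Pairwise co-activation counts ("matrix of addition")
#'
#' For each ROI pair, the number of timepoints at which both ROIs have an
#' event: `counts(i, j) = sum_t e_i(t) e_j(t)`. The diagonal holds the per-ROI
#' event totals, so `counts(i, j) <= min(counts(i, i), counts(j, j))` always.
#'
#' @param raster an `event_raster` from [point_events()].
#' @return an [edge_matrix] of kind `coactivation_count`.
#' @export
coactivation_matrix <- function(raster) {
  counts <- crossprod(unclass(raster))
  edge_matrix(counts, "coactivation_count", roi_labels = colnames(raster))
}

#' Per-ROI upward-crossing counts
#'
#' Number of transitions from at-or-below to strictly above the threshold in
#' each column. Unlike the `"upcrossing"` event mode, the first sample never
#' counts: a crossing needs a preceding sub-threshold sample.
#'
#' @param zts a z-scored [roi_ts].
#' @param threshold_sigma threshold in SD units (default 1).
#' @return named integer vector of per-ROI counts.
#' @examples
#' # a series visiting above the threshold twice has 2 upward crossings
#' @export
upcrossing_count <- function(zts, threshold_sigma = 1) {
  m <- unclass(as_roi_ts(zts))
  above <- m > threshold_sigma
  counts <- colSums(above[-1L, , drop = FALSE] & !above[-nrow(m), , drop = FALSE])
  stats::setNames(as.integer(counts), colnames(m))
}
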