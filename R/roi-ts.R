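#' ROI time-series matrix
#'
#' Construct a validated per-subject BOLD time-series matrix: `T` timepoints
#' (rows) by `N` regions of interest (columns), with unique ROI labels and the
#' repetition time `tr` in seconds. Column order is significant: it defines the
#' edge indexing used by every downstream connectivity matrix.
#'
#' @param values numeric `T x N` matrix; all entries must be finite.
#' @param roi_labels character vector of length `N`; unique, non-empty.
#'   Defaults to the column names of `values`.
#' @param tr repetition time in seconds (sampling interval), positive.
#' @param subject_id optional subject identifier.
#' @return an object of class `roi_ts`: the numeric matrix with attributes
#'   `tr` and `subject_id`, and ROI labels as column names.
#' @examples
#' ts <- roi_ts(matrix(rnorm(40), 10, 4), tr = 3)
#' dim(ts)
#' @export
roi_ts <- function(values, roi_labels = colnames(values), tr = 3,
                   subject_id = NA_character_) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("time-series values must be numeric")
  if (nrow(values) < 2L) stop("need at least 2 timepoints")
  if (ncol(values) < 2L) stop("need at least 2 ROIs")
  if (is.null(roi_labels)) roi_labels <- sprintf("ROI%03d", seq_len(ncol(values)))
  roi_labels <- as.character(roi_labels)
  if (length(roi_labels) != ncol(values))
    stop("roi_labels length does not match number of columns")
  if (anyDuplicated(roi_labels))
    stop("duplicate ROI labels: ",
         paste(unique(roi_labels[duplicated(roi_labels)]), collapse = ", "))
  bad <- which(!is.finite(values))
  if (length(bad)) {
    rc <- arrayInd(bad[1L], dim(values))
    stop(sprintf("non-finite value at timepoint %d, ROI '%s'",
                 rc[1L], roi_labels[rc[2L]]))
  }
  if (!is.numeric(tr) || length(tr) != 1L || !is.finite(tr) || tr <= 0)
    stop("tr must be a positive number of seconds")
  dimnames(values) <- list(NULL, roi_labels)
  structure(values, tr = as.numeric(tr),
            subject_id = as.character(subject_id),
            class = c("roi_ts", class(matrix())))
}

#' @export
print.roi_ts <- function(x, ...) {
  cat(sprintf("ROI time series: %d timepoints x %d ROIs (TR = %g s, %g s total)\n",
              nrow(x), ncol(x), attr(x, "tr"), nrow(x) * attr(x, "tr")))
  if (!is.na(attr(x, "subject_id")))
    cat("  subject:", attr(x, "subject_id"), "\n")
  cat("  ROIs:", paste(utils::head(colnames(x), 5L), collapse = ", "),
      if (ncol(x) > 5L) "..." else "", "\n")
  invisible(x)
}

# keep roi_ts attributes when a function returns a plain matrix of same shape
restore_ts <- function(values, template) {
  roi_ts(values, roi_labels = colnames(template), tr = attr(template, "tr"),
         subject_id = attr(template, "subject_id"))
}

#' Column-wise z-scoring
#'
#' Standardize each ROI series to mean 0 and sample standard deviation 1
#' (denominator `T - 1`). The point-process threshold is defined on this scale,
#' so 1 sigma is exactly 1.0 after `zscore()`.
#'
#' @param ts a [roi_ts] matrix.
#' @return a [roi_ts] with every column standardized.
#' @seealso [point_events()], [bandpass()]
#' @export
zscore <- function(ts) {
  ts <- as_roi_ts(ts)
  sds <- apply(ts, 2L, stats::sd)
  if (any(sds == 0))
    stop("constant ROI series cannot be z-scored: ",
         paste(colnames(ts)[sds == 0], collapse = ", "))
  centred <- sweep(unclass(ts), 2L, colMeans(ts), "-")
  restore_ts(sweep(centred, 2L, sds, "/"), ts)
}

as_roi_ts <- function(x, tr = 3) {
  if (inherits(x, "roi_ts")) x else roi_ts(x, tr = tr)
}

#' Zero-phase temporal band-pass filter
#'
#' Apply the same zero-phase (forward-backward) Butterworth band-pass filter to
#' every ROI column. Because the filter is identical across columns it does not
#' distort the instantaneous cross-correlation structure. With `low = 0` the
#' filter degenerates to a low-pass.
#'
#' @param ts a [roi_ts] matrix.
#' @param low,high passband edges in Hz; `0 <= low < high < 1/(2 tr)`.
#' @param order Butterworth design order (default 2; the two-pass application
#'   doubles the effective order).
#' @return the filtered [roi_ts].
#' @details A warning is emitted when `low > 0` but `1/low` exceeds the record
#'   duration: such a low edge cannot be resolved on the record and acts as a
#'   detrend rather than a band edge.
#' @examples
#' ts <- roi_ts(matrix(rnorm(280), 140, 2), tr = 3)
#' filtered <- bandpass(ts, 0.01, 0.05)
#' @export
bandpass <- function(ts, low, high, order = 2L) {
  ts <- as_roi_ts(ts)
  tr <- attr(ts, "tr")
  nyq <- 1 / (2 * tr)
  if (!(low >= 0 && low < high)) stop("need 0 <= low < high")
  if (high >= nyq)
    stop(sprintf("high edge %g Hz is at or above the Nyquist frequency %g Hz",
                 high, nyq))
  dur <- nrow(ts) * tr
  if (low > 0 && 1 / low > dur)
    warning(sprintf(
      "low edge %g Hz has period %g s, longer than the %g s record; it acts as a detrend",
      low, 1 / low, dur))
  flt <- if (low > 0)
    signal::butter(order, c(low, high) / nyq, type = "pass")
  else
    signal::butter(order, high / nyq, type = "low")
  out <- apply(unclass(ts), 2L, function(col) signal::filtfilt(flt, col))
  restore_ts(out, ts)
}
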