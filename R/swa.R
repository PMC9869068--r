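#' Sliding-window layout
#'
#' Half-open windows `[s, s + w)` starting at `s = 0, step, 2 step, ...`
#' (0-based); trailing partial windows are discarded, so the number of windows
#' is `floor((T - w) / step) + 1`.
#'
#' @param n_timepoints record length `T`.
#' @param length_tp window length `w` in timepoints (`2 <= w <= T`).
#' @param step_tp step between window starts (default 1, maximally
#'   overlapping).
#' @return a `window_spec` list with 1-based `starts`, `length_tp`, `step_tp`
#'   and `n_windows`.
#' @examples
#' make_windows(140, 30)$n_windows  # 111
#' @export
make_windows <- function(n_timepoints, length_tp, step_tp = 1L) {
  if (length_tp < 2L) stop("window length must be >= 2")
  if (length_tp > n_timepoints)
    stop("window length exceeds the record length")
  if (step_tp < 1L) stop("step must be >= 1")
  n_windows <- floor((n_timepoints - length_tp) / step_tp) + 1L
  starts <- 1L + step_tp * (seq_len(n_windows) - 1L)
  structure(list(starts = starts, length_tp = as.integer(length_tp),
                 step_tp = as.integer(step_tp),
                 n_windows = as.integer(n_windows)),
            class = "window_spec")
}

#' Sliding-window functional connectivity
#'
#' Pearson FC within each window, yielding one connectivity matrix per window
#' with the same edge indexing as the static FC.
#'
#' @param ts a [roi_ts].
#' @param spec a [make_windows()] layout (or a window length, taken at step 1).
#' @return list of [edge_matrix] (`pearson_r`), one per window.
#' @export
windowed_fc <- function(ts, spec) {
  ts <- as_roi_ts(ts)
  if (is.numeric(spec)) spec <- make_windows(nrow(ts), spec)
  lapply(seq_along(spec$starts), function(widx) {
    s <- spec$starts[widx]
    seg <- unclass(ts)[s:(s + spec$length_tp - 1L), , drop = FALSE]
    sds <- apply(seg, 2L, stats::sd)
    if (any(sds == 0))
      stop(sprintf("constant ROI series '%s' inside window %d (start %d)",
                   colnames(ts)[sds == 0][1L], widx, s))
    r <- stats::cor(seg)
    r[r > 1] <- 1; r[r < -1] <- -1
    diag(r) <- 1
    edge_matrix(r, "pearson_r", roi_labels = colnames(ts))
  })
}

#' Variability of FC across windows
#'
#' Entry-wise sample standard deviation of the windowed correlation matrices:
#' the edge-level temporal-variability measure. Diagonal is 0 by convention.
#'
#' @param stack list of `pearson_r` [edge_matrix] from [windowed_fc()]
#'   (>= 2 windows).
#' @return an [edge_matrix] of kind `sd_across_windows`.
#' @export
fc_variability <- function(stack) {
  if (length(stack) < 2L) stop("need at least 2 windows to compute an SD")
  arr <- simplify2array(lapply(stack, unclass))
  sd_mat <- apply(arr, c(1L, 2L), stats::sd)
  diag(sd_mat) <- 0
  edge_matrix(sd_mat, "sd_across_windows", roi_labels = colnames(stack[[1L]]))
}

#' Window-length sensitivity assessment
#'
#' For every window length `w` from `w_min` to `w_max` (step-1 sliding
#' windows): the mean correlation over all edges and windows, the mean over
#' edges of the SD across windows, and the differences of both from the
#' full-length static values. At `w = T` the mean equals the static global
#' mean exactly and the SD is 0 (a single window has no dispersion), so both
#' difference curves are exactly zero there.
#'
#' @param ts a [roi_ts].
#' @param w_min,w_max window-length range in timepoints (defaults 5 and `T`).
#' @param increment window-length increment (default 1).
#' @return data.frame of class `window_assessment`: columns `w`, `mean_fc`,
#'   `mean_sd`, `diff_fc`, `diff_sd`.
#' @export
window_size_assessment <- function(ts, w_min = 5L, w_max = nrow(ts),
                                   increment = 1L) {
  ts <- as_roi_ts(ts)
  T_ <- nrow(ts)
  if (w_max > T_) stop("w_max exceeds the record length")
  static <- pearson_fc(ts)
  static_mean <- global_mean_fc(static)
  ws <- seq.int(w_min, w_max, by = increment)
  mean_fc <- numeric(length(ws)); mean_sd <- numeric(length(ws))
  for (idx in seq_along(ws)) {
    w <- ws[idx]
    stack <- windowed_fc(ts, make_windows(T_, w))
    ups <- vapply(stack, function(m) m[upper.tri(m)],
                  numeric(sum(upper.tri(static))))
    ups <- matrix(ups, ncol = length(stack))
    mean_fc[idx] <- mean(ups)
    mean_sd[idx] <- if (length(stack) >= 2L)
      mean(apply(ups, 1L, stats::sd)) else 0
  }
  out <- data.frame(w = ws, mean_fc = mean_fc, mean_sd = mean_sd,
                    diff_fc = mean_fc - static_mean,
                    diff_sd = mean_sd - 0)
  class(out) <- c("window_assessment", "data.frame")
  out
}

#' @export
plot.window_assessment <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(x$w, x$mean_fc, type = "l", xlab = "window length (tp)",
                 ylab = "mean FC", main = "Global FC vs window size", ...)
  graphics::plot(x$w, x$mean_sd, type = "l", xlab = "window length (tp)",
                 ylab = "mean SD across windows", main = "Variability vs window size", ...)
  graphics::plot(x$w, x$diff_fc, type = "l", xlab = "window length (tp)",
                 ylab = "difference from static", main = "FC difference")
  graphics::abline(h = 0, lty = 2)
  graphics::plot(x$w, x$diff_sd, type = "l", xlab = "window length (tp)",
                 ylab = "difference from 0", main = "SD difference")
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}
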