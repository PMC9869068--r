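#' Read a ROI time-series file
#'
#' Time-series files are tab-separated text: one header row of ROI labels
#' followed by `T` numeric rows of width `N`. The repetition time is not stored
#' in the file; supply it via `tr` (it usually comes from a run configuration
#' or a command-line flag).
#'
#' @param path file to read.
#' @param tr repetition time in seconds.
#' @param subject_id optional subject identifier attached to the result.
#' @return a [roi_ts].
#' @export
read_timeseries <- function(path, tr = 3, subject_id = NA_character_) {
  if (!file.exists(path)) stop("time-series file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 3L) stop("time-series file needs a header and >= 2 rows: ", path)
  labels <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  rows <- strsplit(lines[-1L], "\t", fixed = TRUE)
  widths <- lengths(rows)
  if (any(widths != length(labels)))
    stop(sprintf("ragged row %d in %s: %d cells, expected %d",
                 which(widths != length(labels))[1L] + 1L, path,
                 widths[widths != length(labels)][1L], length(labels)))
  values <- matrix(NA_real_, length(rows), length(labels))
  for (r in seq_along(rows)) {
    v <- suppressWarnings(as.numeric(rows[[r]]))
    bad <- which(is.na(v) | rows[[r]] == "")
    if (length(bad))
      stop(sprintf("non-numeric or blank cell at data row %d, ROI '%s' in %s",
                   r, labels[bad[1L]], path))
    values[r, ] <- v
  }
  roi_ts(values, roi_labels = labels, tr = tr, subject_id = subject_id)
}

#' Write a ROI time-series file
#'
#' @param ts a [roi_ts].
#' @param path destination; tab-separated, header row of ROI labels, one row
#'   per timepoint. Values are written with 15 significant digits so a
#'   write/read round trip is lossless to at least 12 significant digits.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(ts, path) {
  ts <- as_roi_ts(ts)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(colnames(ts), collapse = "\t"), con)
  body <- apply(unclass(ts), 1L, function(r)
    paste(formatC(r, digits = 15, format = "g"), collapse = "\t"))
  writeLines(body, con)
  invisible(path)
}

#' Read a cohort manifest
#'
#' A manifest is a CSV with columns `subject_id`, `group`, `path`. Group order
#' defaults to first appearance in the file; pass `group_order` to fix it
#' (e.g. `c("HC", "EMCI", "LMCI", "AD")`).
#'
#' @param path manifest CSV.
#' @param group_order optional character vector of group labels defining the
#'   group ordering used in all summaries and comparisons.
#' @return a data.frame of class `cohort_manifest` with a `group` factor.
#' @export
read_manifest <- function(path, group_order = NULL) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "group", "path")
  if (!all(need %in% names(df)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  cohort_manifest(df[need], group_order = group_order)
}

#' Construct a cohort manifest
#'
#' @param df data.frame with columns `subject_id`, `group`, `path`.
#' @param group_order optional ordering of group labels; defaults to first
#'   appearance.
#' @return the validated `cohort_manifest`.
#' @export
cohort_manifest <- function(df, group_order = NULL) {
  if (anyDuplicated(df$subject_id))
    stop("duplicate subject_id: ",
         paste(unique(df$subject_id[duplicated(df$subject_id)]), collapse = ", "))
  if (any(is.na(df$group) | df$group == ""))
    stop("empty group label for subject ",
         df$subject_id[which(is.na(df$group) | df$group == "")[1L]])
  if (is.null(group_order)) group_order <- unique(df$group)
  if (!all(df$group %in% group_order))
    stop("groups not in group_order: ",
         paste(setdiff(df$group, group_order), collapse = ", "))
  df$group <- factor(df$group, levels = group_order)
  class(df) <- c("cohort_manifest", "data.frame")
  df
}

#' Write a cohort manifest
#' @param manifest a `cohort_manifest`.
#' @param path destination CSV.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  out <- data.frame(subject_id = manifest$subject_id,
                    group = as.character(manifest$group),
                    path = manifest$path)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Load every subject of a manifest and validate cohort integrity
#'
#' Loads each subject's time series and checks that all subjects share an
#' identical ROI label sequence (order matters: it defines edge indexing),
#' the same number of timepoints and the same TR, and that every group has at
#' least two subjects. Subjects whose files are missing are reported by id,
#' mirroring the practice of excluding participants with missing series before
#' any analysis.
#'
#' @param manifest a `cohort_manifest`.
#' @param tr repetition time passed to [read_timeseries()].
#' @param base_dir optional directory against which relative manifest paths are
#'   resolved.
#' @return an `fc_cohort`: list with `series` (named list of [roi_ts]) and
#'   `manifest`.
#' @export
read_cohort <- function(manifest, tr = 3, base_dir = NULL) {
  paths <- manifest$path
  if (!is.null(base_dir)) paths <- file.path(base_dir, paths)
  missing <- !file.exists(paths)
  if (any(missing))
    stop("missing time-series file for subject(s): ",
         paste(manifest$subject_id[missing], collapse = ", "))
  series <- Map(function(p, id) read_timeseries(p, tr = tr, subject_id = id),
                paths, manifest$subject_id)
  names(series) <- manifest$subject_id
  cohort <- fc_cohort(series, manifest)
  report <- validate_cohort(cohort)
  if (nrow(report)) {
    stop("cohort validation failed:\n",
         paste(sprintf("  %s: %s", report$subject_id, report$problem),
               collapse = "\n"))
  }
  cohort
}

#' Bundle loaded series and manifest into a cohort object
#' @param series named list of [roi_ts], names = subject ids.
#' @param manifest matching `cohort_manifest`.
#' @return an `fc_cohort` list.
#' @export
fc_cohort <- function(series, manifest) {
  if (!setequal(names(series), manifest$subject_id))
    stop("series names do not match manifest subject ids")
  series <- series[manifest$subject_id]
  structure(list(series = series, manifest = manifest), class = "fc_cohort")
}

#' @export
print.fc_cohort <- function(x, ...) {
  tab <- table(x$manifest$group)
  first <- x$series[[1L]]
  cat(sprintf("Cohort: %d subjects in %d groups (%s)\n",
              length(x$series), length(tab),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  cat(sprintf("  %d timepoints x %d ROIs, TR = %g s\n",
              nrow(first), ncol(first), attr(first, "tr")))
  invisible(x)
}

#' Validate cohort homogeneity
#'
#' Checks every subject against the first: identical ROI labels in identical
#' order, identical number of timepoints, identical TR; and that each group has
#' at least 2 subjects. Returns a report rather than stopping, so callers can
#' decide how to handle offending subjects.
#'
#' @param cohort an `fc_cohort`.
#' @return data.frame with columns `subject_id`, `problem`; zero rows when the
#'   cohort is consistent.
#' @export
validate_cohort <- function(cohort) {
  series <- cohort$series
  ref <- series[[1L]]
  problems <- list()
  for (id in names(series)) {
    s <- series[[id]]
    if (nrow(s) != nrow(ref))
      problems[[length(problems) + 1L]] <-
        data.frame(subject_id = id,
                   problem = sprintf("%d timepoints, expected %d", nrow(s), nrow(ref)))
    if (!identical(colnames(s), colnames(ref)))
      problems[[length(problems) + 1L]] <-
        data.frame(subject_id = id,
                   problem = if (setequal(colnames(s), colnames(ref)))
                     "ROI columns permuted (order is significant)"
                   else "ROI label set differs")
    if (!isTRUE(all.equal(attr(s, "tr"), attr(ref, "tr"))))
      problems[[length(problems) + 1L]] <-
        data.frame(subject_id = id, problem = "TR differs")
  }
  small <- table(cohort$manifest$group) < 2L
  for (g in names(small)[small])
    problems[[length(problems) + 1L]] <-
      data.frame(subject_id = NA_character_,
                 problem = sprintf("group '%s' has fewer than 2 subjects", g))
  if (length(problems)) do.call(rbind, problems)
  else data.frame(subject_id = character(), problem = character())
}

#' Read/write a symmetric edge matrix
#'
#' Matrices are stored full (not triangle-only) as TSV with a header row and a
#' leading label column, and symmetry is re-checked on read.
#'
#' @param m an [edge_matrix].
#' @param path file path.
#' @param metric_kind metric kind expected on read.
#' @return `write_edge_matrix`: `path` invisibly; `read_edge_matrix`: the
#'   [edge_matrix].
#' @export
write_edge_matrix <- function(m, path) {
  df <- data.frame(roi = rownames(m),
                   formatC(unclass(m), digits = 15, format = "g"),
                   check.names = FALSE)
  names(df) <- c("roi", colnames(m))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_edge_matrix
#' @export
read_edge_matrix <- function(path, metric_kind = "pearson_r") {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  labels <- df[[1L]]
  values <- as.matrix(df[, -1L, drop = FALSE])
  if (!identical(colnames(values), labels))
    stop("row and column ROI labels disagree in ", path)
  edge_matrix(values, metric_kind = metric_kind, roi_labels = labels)
}

#' Write an edge-wise result table
#'
#' Long-format TSV twin of the per-edge statistics tables: one row per edge and
#' post-hoc pair (edges without post-hoc rows carry `NA` in the pair columns).
#'
#' @param fit an [edgewise_anova] fit.
#' @param path destination TSV.
#' @return `path`, invisibly.
#' @export
write_result_table <- function(fit, path) {
  utils::write.table(result_table(fit), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
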