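#' Pipeline run configuration
#'
#' Collects every tunable of the end-to-end pipeline in one plain list that is
#' serialized verbatim into the output directory, so a run is reproducible
#' from its saved configuration alone.
#'
#' @param out_dir output directory.
#' @param seed master seed; all randomness (cohort simulation) derives from it.
#' @param stages character subset of
#'   `c("simulate", "fc", "swa", "ppa", "graph", "stats")`; omitted stages are
#'   skipped and the statistics stage restricts itself to the metrics actually
#'   computed.
#' @param manifest path of a cohort manifest CSV; required when `"simulate"`
#'   is not among the stages.
#' @param tr repetition time in seconds for data read from disk.
#' @param n_per_group,n_rois,n_timepoints,passband_hz simulated-cohort
#'   conditions (see [generator_config()]).
#' @param effects list of [planted_effect]s for the simulated cohort.
#' @param band optional length-2 preprocessing passband in Hz; `NULL` (the
#'   default) skips temporal filtering, for data assumed already preprocessed.
#' @param window,step sliding-window length and step in timepoints.
#' @param assess logical; also run the window-length assessment on the first
#'   subject and write the curves.
#' @param ppa_threshold,ppa_mode point-process threshold (SD units) and event
#'   mode.
#' @param graph_threshold binarization threshold for the network measures.
#' @param sweep logical; also run the 0.1-0.5 threshold sweep per subject.
#' @param alpha,family_scope screen level and Bonferroni family for
#'   [edgewise_anova()].
#' @param write_matrices logical; write per-subject matrices as TSV.
#' @return a `run_config` list.
#' @export
run_config <- function(out_dir, seed = 1L,
                       stages = c("simulate", "fc", "swa", "ppa", "graph",
                                  "stats"),
                       manifest = NULL, tr = 3,
                       n_per_group = c(HC = 10L, EMCI = 10L, LMCI = 10L,
                                       AD = 10L),
                       n_rois = 20L, n_timepoints = 140L,
                       passband_hz = c(0.01, 0.05), effects = list(),
                       band = NULL, window = 30L, step = 1L, assess = FALSE,
                       ppa_threshold = 1, ppa_mode = "point",
                       graph_threshold = 0.3, sweep = FALSE,
                       alpha = 0.05, family_scope = "posthoc_only",
                       write_matrices = TRUE) {
  stages <- match.arg(stages, several.ok = TRUE)
  if (!"simulate" %in% stages && is.null(manifest))
    stop("a manifest is required when the simulate stage is disabled")
  structure(list(out_dir = out_dir, seed = as.integer(seed), stages = stages,
                 manifest = manifest, tr = tr, n_per_group = n_per_group,
                 n_rois = n_rois, n_timepoints = n_timepoints,
                 passband_hz = passband_hz, effects = effects, band = band,
                 window = window, step = step, assess = assess,
                 ppa_threshold = ppa_threshold, ppa_mode = ppa_mode,
                 graph_threshold = graph_threshold, sweep = sweep,
                 alpha = alpha, family_scope = family_scope,
                 write_matrices = write_matrices),
            class = "run_config")
}

#' Serialize / restore a run configuration
#'
#' Plain `key = value` text, one key per line, vectors comma-joined; planted
#' effects as `group:roi_i:roi_j:target_r` tuples.
#'
#' @param config a [run_config].
#' @param path file path.
#' @return `write_run_config`: `path` invisibly; `read_run_config`: the
#'   restored `run_config`.
#' @export
write_run_config <- function(config, path) {
  fmt <- function(v) {
    if (is.null(v)) return("")
    if (!is.null(names(v)) && any(nzchar(names(v))))
      paste(sprintf("%s=%s", names(v), v), collapse = ",")
    else paste(v, collapse = ",")
  }
  keys <- setdiff(names(config), "effects")
  lines <- vapply(keys, function(k) sprintf("%s = %s", k, fmt(config[[k]])),
                  character(1L))
  eff <- vapply(config$effects, function(e)
    sprintf("effect = %s:%s:%s:%g", e$group, e$roi_i, e$roi_j, e$target_r),
    character(1L))
  writeLines(c(lines, eff), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  kv <- regmatches(lines, regexec("^([a-z_]+) *= *(.*)$", lines))
  out <- list(); effects <- list()
  for (m in kv) {
    key <- m[2L]; val <- trimws(m[3L])
    if (key == "effect") {
      parts <- strsplit(val, ":", fixed = TRUE)[[1L]]
      effects[[length(effects) + 1L]] <-
        planted_effect(parts[1L], parts[2L], parts[3L], as.numeric(parts[4L]))
    } else out[[key]] <- val
  }
  parse_num <- function(s) {
    v <- strsplit(s, ",", fixed = TRUE)[[1L]]
    if (all(grepl("=", v, fixed = TRUE))) {
      p <- strsplit(v, "=", fixed = TRUE)
      stats::setNames(as.numeric(vapply(p, `[`, "", 2L)),
                      vapply(p, `[`, "", 1L))
    } else as.numeric(v)
  }
  run_config(out_dir = out$out_dir, seed = as.integer(out$seed),
             stages = strsplit(out$stages, ",")[[1L]],
             manifest = if (nzchar(out$manifest)) out$manifest else NULL,
             tr = as.numeric(out$tr),
             n_per_group = parse_num(out$n_per_group),
             n_rois = as.integer(out$n_rois),
             n_timepoints = as.integer(out$n_timepoints),
             passband_hz = parse_num(out$passband_hz), effects = effects,
             band = if (nzchar(out$band)) parse_num(out$band) else NULL,
             window = as.integer(out$window), step = as.integer(out$step),
             assess = as.logical(out$assess),
             ppa_threshold = as.numeric(out$ppa_threshold),
             ppa_mode = out$ppa_mode,
             graph_threshold = as.numeric(out$graph_threshold),
             sweep = as.logical(out$sweep), alpha = as.numeric(out$alpha),
             family_scope = out$family_scope,
             write_matrices = as.logical(out$write_matrices))
}

#' Run the whole pipeline
#'
#' Orchestrates simulate (or load) -> z-score (and optional band-pass) ->
#' static FC / sliding-window variability / point-process co-activation /
#' graph metrics -> group statistics, writing every artifact under
#' `config$out_dir`. Identical configurations produce bit-identical result
#' tables.
#'
#' @param config a [run_config].
#' @return invisibly, a list of result objects (`fits`, `scalar_table`,
#'   `graph_records`, `cohort`) with file paths in `paths`.
#' @export
run_pipeline <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  write_run_config(config, file.path(config$out_dir, "run_config.txt"))
  stages <- config$stages
  paths <- list(config = file.path(config$out_dir, "run_config.txt"))

  if ("simulate" %in% stages) {
    gen <- generator_config(n_per_group = config$n_per_group,
                            n_rois = config$n_rois,
                            n_timepoints = config$n_timepoints,
                            tr_seconds = config$tr,
                            passband_hz = config$passband_hz,
                            seed = config$seed)
    cohort <- simulate_cohort(gen, effects = config$effects)
    data_dir <- file.path(config$out_dir, "data")
    paths$manifest <- write_cohort(cohort, data_dir)
  } else {
    manifest <- read_manifest(config$manifest)
    cohort <- read_cohort(manifest, tr = config$tr,
                          base_dir = dirname(config$manifest))
  }
  manifest <- cohort$manifest
  prep <- lapply(cohort$series, function(s) {
    if (!is.null(config$band))
      s <- bandpass(s, config$band[1L], config$band[2L])
    zscore(s)
  })

  matrices <- list(); scalar_rows <- list()
  mat_dir <- file.path(config$out_dir, "matrices")
  if (config$write_matrices) dir.create(mat_dir, showWarnings = FALSE)
  emit <- function(m, id, tag) {
    if (config$write_matrices)
      write_edge_matrix(m, file.path(mat_dir, sprintf("%s_%s.tsv", id, tag)))
    m
  }

  if ("fc" %in% stages) {
    matrices$pearson_r <- Map(function(s, id)
      emit(pearson_fc(s), id, "fc"), prep, manifest$subject_id)
    scalar_rows$global_fc <- data.frame(
      measure = "global_mean_fc",
      value = vapply(matrices$pearson_r, global_mean_fc, numeric(1L)),
      group = manifest$group)
  }
  if ("swa" %in% stages) {
    spec <- make_windows(config$n_timepoints, config$window, config$step)
    matrices$sd_across_windows <- Map(function(s, id)
      emit(fc_variability(windowed_fc(s, spec)), id, "swa_sd"),
      prep, manifest$subject_id)
    scalar_rows$global_sd <- data.frame(
      measure = "global_mean_sd_across_windows",
      value = vapply(matrices$sd_across_windows, global_mean_fc, numeric(1L)),
      group = manifest$group)
    if (config$assess) {
      curve <- window_size_assessment(prep[[1L]])
      paths$assessment <- file.path(config$out_dir, "window_assessment.tsv")
      utils::write.table(curve, paths$assessment, sep = "\t",
                         row.names = FALSE, quote = FALSE)
    }
  }
  if ("ppa" %in% stages) {
    matrices$coactivation_count <- Map(function(s, id)
      emit(coactivation_matrix(
        point_events(s, config$ppa_threshold, config$ppa_mode)), id, "ppa"),
      prep, manifest$subject_id)
    scalar_rows$global_ppa <- data.frame(
      measure = "global_mean_coactivation",
      value = vapply(matrices$coactivation_count, global_mean_fc, numeric(1L)),
      group = manifest$group)
  }
  graph_records <- NULL
  if ("graph" %in% stages) {
    fcs <- if (!is.null(matrices$pearson_r)) matrices$pearson_r
    else Map(function(s, id) pearson_fc(s), prep, manifest$subject_id)
    graph_records <- do.call(rbind, Map(function(m, id)
      graph_metrics(m, config$graph_threshold, id), fcs, manifest$subject_id))
    paths$graph <- file.path(config$out_dir, "graph_metrics.tsv")
    utils::write.table(graph_records, paths$graph, sep = "\t",
                       row.names = FALSE, quote = FALSE)
    if (config$sweep) {
      sweeps <- do.call(rbind, Map(function(m, id)
        threshold_sweep(m, subject_id = id), fcs, manifest$subject_id))
      paths$sweep <- file.path(config$out_dir, "threshold_sweep.tsv")
      utils::write.table(sweeps, paths$sweep, sep = "\t",
                         row.names = FALSE, quote = FALSE)
    }
    for (meas in c("char_path_length", "mean_clustering", "mean_degree"))
      scalar_rows[[meas]] <- data.frame(measure = meas,
                                        value = graph_records[[meas]],
                                        group = manifest$group)
  }
  fits <- list(); scalar_table <- NULL
  if ("stats" %in% stages) {
    for (kind in names(matrices)) {
      fit <- edgewise_anova(matrices[[kind]], manifest$group,
                            alpha = config$alpha,
                            family_scope = config$family_scope)
      fits[[kind]] <- fit
      paths[[paste0("edges_", kind)]] <-
        file.path(config$out_dir, sprintf("edge_results_%s.tsv", kind))
      write_result_table(fit, paths[[paste0("edges_", kind)]])
    }
    if (length(scalar_rows)) {
      scalar_table <- scalar_anova_table(do.call(rbind, scalar_rows),
                                         alpha = config$alpha)
      paths$scalar <- file.path(config$out_dir, "scalar_results.tsv")
      utils::write.table(scalar_table, paths$scalar, sep = "\t",
                         row.names = FALSE, quote = FALSE)
    }
  }
  log_lines <- c(sprintf("restfc %s",
                         as.character(utils::packageVersion("restfc"))),
                 R.version.string,
                 sprintf("seed %d", config$seed),
                 sprintf("stages %s", paste(stages, collapse = ",")),
                 sprintf("subjects %d", nrow(manifest)))
  writeLines(log_lines, file.path(config$out_dir, "run_log.txt"))
  invisible(list(fits = fits, scalar_table = scalar_table,
                 graph_records = graph_records, cohort = cohort,
                 paths = paths))
}
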