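# End-to-end orchestration: simulate or load a cohort, preprocess, extract
# features, select relevant ones per one-vs-rest problem, aggregate, and
# write artifacts plus a JSON run summary. Reruns with identical config and
# seed are bit-identical.

#' Pipeline configuration
#'
#' @param input_dir directory containing a `manifest.csv` and the recording
#'   files it points to; `NULL` (default) simulates a cohort instead.
#' @param simulation a [simulation_config()] used when `input_dir` is `NULL`.
#' @param threshold_frac crop threshold fraction (default 0.10).
#' @param fdr_q FDR level per binary problem (default 0.05).
#' @param catalog_size features per series; `NULL` = core catalogue.
#' @param smoothing apply Savitzky-Golay trajectory smoothing before
#'   differentiation (see [smooth_recording()]); default `FALSE`.
#' @param seed master seed.
#' @param output_dir directory for artifacts; `NULL` keeps results in memory.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(input_dir = NULL, simulation = simulation_config(),
                            threshold_frac = 0.10, fdr_q = 0.05,
                            catalog_size = NULL, smoothing = FALSE,
                            seed = 1L, output_dir = NULL) {
  if (threshold_frac <= 0 || threshold_frac >= 1) {
    stop("threshold_frac must be in (0, 1)", call. = FALSE)
  }
  if (fdr_q <= 0 || fdr_q >= 1) stop("fdr_q must be in (0, 1)", call. = FALSE)
  if (is.null(input_dir)) {
    simulation$seed <- as.integer(seed)
  }
  structure(list(input_dir = input_dir, simulation = simulation,
                 threshold_frac = threshold_frac, fdr_q = fdr_q,
                 catalog_size = catalog_size, smoothing = isTRUE(smoothing),
                 seed = as.integer(seed), output_dir = output_dir),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Stages: (simulate | load) -> reflect -> crop -> derive -> normalise ->
#' extract features -> one-vs-rest selection with Benjamini-Yekutieli FDR
#' control -> aggregate by marker/axis/domain. If `output_dir` is set, writes
#' the manifest, relevance tables, report CSVs and a `run_summary.json`.
#'
#' @param config a [pipeline_config()].
#' @return list of class `pipeline_result`: `manifest`, `feature_matrix`,
#'   `selection` (a `common_feature_set`), `report`, and `summary` (stage
#'   bookkeeping: recordings in/processed, columns, m per problem, skipped
#'   columns, per-problem and common significant counts, q, seed).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) {
    stop("config must be a pipeline_config", call. = FALSE)
  }
  if (is.null(config$input_dir)) {
    cohort <- simulate_cohort(config$simulation)
    recordings <- cohort$recordings
    manifest <- cohort$manifest
  } else {
    manifest <- read_manifest(file.path(config$input_dir, "manifest.csv"))
    recordings <- lapply(seq_len(nrow(manifest)), function(i) {
      row <- manifest[i, ]
      fmt <- if (grepl("\\.trc$", row$path, ignore.case = TRUE)) "trc" else "csv"
      read_recording(file.path(config$input_dir, row$path), fmt,
                     recording_id = row$recording_id,
                     participant_id = row$participant_id,
                     class_label = row$class_label, side = row$side,
                     activity = row$activity)
    })
    names(recordings) <- manifest$recording_id
  }
  n_in <- length(recordings)
  series_sets <- vector("list", n_in)
  names(series_sets) <- manifest$recording_id
  errors <- character(0)
  for (id in manifest$recording_id) {
    s <- tryCatch(preprocess_recording(recordings[[id]], config$threshold_frac,
                                       smoothing = config$smoothing),
                  error = function(e) e)
    if (inherits(s, "error")) {
      stop(sprintf("preprocessing failed for recording %s: %s",
                   id, conditionMessage(s)), call. = FALSE)
    }
    series_sets[[id]] <- s
  }
  catalog <- feature_catalog(config$catalog_size)
  fm <- build_feature_matrix(series_sets, manifest, catalog)
  sel <- one_vs_rest_common(fm, config$fdr_q)
  report <- aggregate_counts(sel)
  m_per_problem <- vapply(sel$tables, attr, integer(1), "m")
  skipped <- vapply(sel$tables, function(t) {
    attr(t, "n_skipped_constant") + attr(t, "n_skipped_nan")
  }, integer(1))
  summary <- list(
    recordings_in = n_in,
    recordings_processed = n_in - length(errors),
    n_feature_columns = ncol(fm$values),
    catalog_size = length(catalog),
    m_tested = as.list(m_per_problem),
    columns_skipped = as.list(skipped),
    significant = as.list(sel$counts),
    common_count = length(sel$common),
    fdr_q = config$fdr_q,
    threshold_frac = config$threshold_frac,
    smoothing = config$smoothing,
    seed = config$seed)
  result <- structure(list(manifest = manifest, feature_matrix = fm,
                           selection = sel, report = report,
                           summary = summary),
                      class = "pipeline_result")
  if (!is.null(config$output_dir)) {
    dir <- config$output_dir
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_manifest(manifest, file.path(dir, "manifest.csv"))
    for (cl in names(sel$tables)) {
      utils::write.csv(sel$tables[[cl]],
                       file.path(dir, sprintf("relevance_%s.csv", cl)),
                       row.names = FALSE)
    }
    utils::write.csv(
      data.frame(column_id = sel$common,
                 series_name = sel$columns$series_name,
                 feature_name = sel$columns$feature_name),
      file.path(dir, "common_features.csv"), row.names = FALSE)
    export_report(report, dir)
    jsonlite::write_json(summary, file.path(dir, "run_summary.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<pipeline_result> %d recordings, %d feature columns (catalogue %d)\n",
    s$recordings_in, s$n_feature_columns, s$catalog_size))
  cat(sprintf("  significant: G0 %d, G1 %d, G2 %d; common %d (q = %g)\n",
              s$significant$G0, s$significant$G1, s$significant$G2,
              s$common_count, s$fdr_q))
  invisible(x)
}

#' Path to the bundled published-counts worked example
#'
#' A long-format grid of common-significant-feature counts by marker, domain
#' and axis, transcribed from a published upper-limb reach-and-lift study's
#' report table; used as the worked example for the aggregation arithmetic.
#'
#' @return file path of the CSV.
#' @export
published_counts_path <- function() {
  system.file("extdata", "published_common_feature_counts.csv",
              package = "kinfresh", mustWork = TRUE)
}
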