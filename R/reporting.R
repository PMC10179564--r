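# Aggregation of the common significant features by marker, movement axis
# and signal domain, in the grid layout conventional for upper-limb
# kinematic-feature reports (module column split into A/V/D sub-rows,
# trajectory/acceleration/velocity/displacement columns by x/y/z).

DOMAINS <- c("trajectory", "displacement", "velocity", "acceleration")
AXIS_LEVELS <- c("x", "y", "z", "module")

#' Classify a derived-series name into marker, domain and axis
#'
#' The 60-name vocabulary follows the marker-prefix scheme: `Mx/My/Mz`
#' trajectory; `Mdx/Mdy/Mdz` displacement and `MD` its module; `Mvx/Mvy/Mvz`
#' velocity and `MV` speed; `Max/May/Maz` acceleration and `MA` its module.
#' Module series are classified under their kinematic domain with axis
#' `"module"`; trajectory has no module series.
#'
#' @param series_name one of the 60 derived series names.
#' @return list with `marker`, `domain`, `axis`.
#' @export
classify_series_name <- function(series_name) {
  m <- MARKERS[startsWith(series_name, MARKERS)]
  if (length(m) != 1L) stop("unknown series name: ", series_name, call. = FALSE)
  suffix <- substring(series_name, nchar(m) + 1L)
  map <- switch(suffix,
    x = , y = , z = list(domain = "trajectory", axis = suffix),
    dx = , dy = , dz = list(domain = "displacement", axis = substring(suffix, 2)),
    vx = , vy = , vz = list(domain = "velocity", axis = substring(suffix, 2)),
    ax = , ay = , az = list(domain = "acceleration", axis = substring(suffix, 2)),
    D = list(domain = "displacement", axis = "module"),
    V = list(domain = "velocity", axis = "module"),
    A = list(domain = "acceleration", axis = "module"),
    stop("unknown series name: ", series_name, call. = FALSE))
  list(marker = m, domain = map$domain, axis = map$axis)
}

empty_count_array <- function() {
  array(0L, dim = c(length(MARKERS), length(DOMAINS), length(AXIS_LEVELS)),
        dimnames = list(marker = MARKERS, domain = DOMAINS, axis = AXIS_LEVELS))
}

#' Aggregate significant common features by marker, domain and axis
#'
#' Accepts either a [one_vs_rest_common()] result (each common feature
#' contributes 1 to the cell of its parent series) or a long-format count
#' table with columns `marker`, `domain`, `axis`, `count` (e.g. an already
#' tabulated grid).
#'
#' @param x a `common_feature_set` or a data.frame of cell counts.
#' @return list of class `aggregation_report` with `cells` (marker x domain x
#'   axis count array), `marker_totals`, `domain_totals`, `axis_totals`, and
#'   `grand_total`.
#' @export
aggregate_counts <- function(x) {
  cells <- empty_count_array()
  if (inherits(x, "common_feature_set")) {
    for (s in x$columns$series_name) {
      t <- classify_series_name(s)
      cells[t$marker, t$domain, t$axis] <- cells[t$marker, t$domain, t$axis] + 1L
    }
  } else if (is.data.frame(x)) {
    need <- c("marker", "domain", "axis", "count")
    if (!all(need %in% names(x))) {
      stop("count table needs columns marker, domain, axis, count", call. = FALSE)
    }
    for (i in seq_len(nrow(x))) {
      mk <- match.arg(x$marker[i], MARKERS)
      dm <- match.arg(x$domain[i], DOMAINS)
      ax <- match.arg(x$axis[i], AXIS_LEVELS)
      if (dm == "trajectory" && ax == "module") {
        stop("no trajectory-module series exists", call. = FALSE)
      }
      cells[mk, dm, ax] <- cells[mk, dm, ax] + as.integer(x$count[i])
    }
  } else {
    stop("x must be a common_feature_set or a count data.frame", call. = FALSE)
  }
  structure(list(
    cells = cells,
    marker_totals = apply(cells, "marker", sum),
    domain_totals = apply(cells, "domain", sum),
    axis_totals = apply(cells, "axis", sum),
    grand_total = sum(cells)), class = "aggregation_report")
}

#' @export
print.aggregation_report <- function(x, ...) {
  cat(sprintf("<aggregation_report> %d common significant features\n",
              x$grand_total))
  cat("  by marker: ", paste(sprintf("%s %d", names(x$marker_totals),
                                     x$marker_totals), collapse = ", "), "\n")
  cat("  by axis:   ", paste(sprintf("%s %d", names(x$axis_totals),
                                     x$axis_totals), collapse = ", "), "\n")
  cat("  by domain: ", paste(sprintf("%s %d", names(x$domain_totals),
                                     x$domain_totals), collapse = ", "), "\n")
  invisible(x)
}

#' Long (tidy) view of an aggregation report
#'
#' @param report an [aggregate_counts()] result.
#' @return data.frame with columns `marker`, `domain`, `axis`, `count`
#'   (60 rows: the four trajectory-module cells are structural zeros and
#'   omitted).
#' @export
report_long <- function(report) {
  g <- expand.grid(marker = MARKERS, domain = DOMAINS, axis = AXIS_LEVELS,
                   stringsAsFactors = FALSE)
  g <- g[!(g$domain == "trajectory" & g$axis == "module"), ]
  g$count <- mapply(function(m, d, a) report$cells[m, d, a],
                    g$marker, g$domain, g$axis)
  rownames(g) <- NULL
  g
}

#' Wide grid view of an aggregation report
#'
#' Renders the conventional report grid: one row per marker and axis, the
#' module column split by acceleration/velocity/displacement, and the four
#' per-axis domains as columns.
#'
#' @param report an [aggregate_counts()] result.
#' @return data.frame with columns `marker`, `module`, `module_domain`,
#'   `trajectory`, `acceleration`, `velocity`, `displacement`, `axis`.
#' @export
report_wide <- function(report) {
  rows <- list()
  module_order <- c("acceleration", "velocity", "displacement")
  for (m in MARKERS) {
    for (i in 1:3) {
      ax <- AXES[i]
      rows[[length(rows) + 1L]] <- data.frame(
        marker = m,
        module = report$cells[m, module_order[i], "module"],
        module_domain = c("A", "V", "D")[i],
        trajectory = report$cells[m, "trajectory", ax],
        acceleration = report$cells[m, "acceleration", ax],
        velocity = report$cells[m, "velocity", ax],
        displacement = report$cells[m, "displacement", ax],
        axis = toupper(ax), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Per-feature class summaries (boxplot-ready)
#'
#' @param fm a [build_feature_matrix()] result.
#' @param column_ids feature columns to summarise.
#' @return data.frame with one row per (column, class): min, first quartile,
#'   median, third quartile, max, n.
#' @export
feature_class_summary <- function(fm, column_ids) {
  missing <- setdiff(column_ids, fm$columns$column_id)
  if (length(missing)) {
    stop("unknown feature column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  rows <- list()
  for (id in column_ids) {
    v <- fm$values[, id]
    for (cl in CLASS_LABELS) {
      vv <- v[fm$class_labels == cl & !is.nan(v)]
      qs <- if (length(vv)) stats::quantile(vv, c(0, 0.25, 0.5, 0.75, 1),
                                            type = 7)
            else rep(NA_real_, 5)
      rows[[length(rows) + 1L]] <- data.frame(
        column_id = id, class_label = cl, n = length(vv),
        min = qs[1], q1 = qs[2], median = qs[3], q3 = qs[4], max = qs[5],
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Export report artifacts as CSV
#'
#' Writes the wide grid, the long cell counts, the marginal summaries and,
#' optionally, per-feature class summaries.
#'
#' @param report an [aggregate_counts()] result.
#' @param dir output directory (created if needed).
#' @param fm optional feature matrix for class summaries.
#' @param summary_columns feature columns to summarise (requires `fm`).
#' @return character vector of written paths, invisibly.
#' @export
export_report <- function(report, dir, fm = NULL, summary_columns = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    wide = file.path(dir, "report_grid.csv"),
    long = file.path(dir, "report_cells.csv"),
    marginals = file.path(dir, "report_marginals.csv"))
  utils::write.csv(report_wide(report), paths[["wide"]], row.names = FALSE)
  utils::write.csv(report_long(report), paths[["long"]], row.names = FALSE)
  marg <- rbind(
    data.frame(dimension = "marker", level = names(report$marker_totals),
               count = as.integer(report$marker_totals)),
    data.frame(dimension = "axis", level = names(report$axis_totals),
               count = as.integer(report$axis_totals)),
    data.frame(dimension = "domain", level = names(report$domain_totals),
               count = as.integer(report$domain_totals)),
    data.frame(dimension = "total", level = "all",
               count = report$grand_total))
  utils::write.csv(marg, paths[["marginals"]], row.names = FALSE)
  if (!is.null(summary_columns)) {
    if (is.null(fm)) stop("feature matrix required for class summaries",
                          call. = FALSE)
    p <- file.path(dir, "feature_class_summary.csv")
    utils::write.csv(feature_class_summary(fm, summary_columns), p,
                     row.names = FALSE)
    paths <- c(paths, summary = p)
  }
  invisible(paths)
}
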