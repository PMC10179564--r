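# Scalar feature catalogue and extraction: every derived series is mapped to
# named real-valued or binary features, forming the recordings x features
# matrix the relevance tests operate on.
#
# Conventions pinned here (and in tests): moments use population (biased)
# variance; autocorrelation divides the lagged autocovariance by n times the
# population variance (the stats::acf convention); quantiles are type-7;
# location-of-extremum features are relative positions in [0, 1]. Features
# undefined on a series (e.g. autocorrelation of a constant series) return
# NaN, which is retained and flagged rather than dropped silently.

feature_def <- function(name, kind, fun) {
  list(name = name, kind = kind, fun = fun)
}

# shared per-series precomputations
series_pre <- function(x) {
  n <- length(x)
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  list(n = n, mean = mu, var_pop = m2, sd_pop = sqrt(m2),
       min = min(x), max = max(x), range = max(x) - min(x),
       diffs = diff(x))
}

f_autocorrelation <- function(lag) {
  force(lag)
  function(x, p) {
    if (p$n <= lag || p$var_pop == 0) return(NaN)
    i <- seq_len(p$n - lag)
    sum((x[i] - p$mean) * (x[i + lag] - p$mean)) / (p$n * p$var_pop)
  }
}

f_number_of_peaks <- function(support) {
  force(support)
  function(x, p) {
    n <- p$n
    if (n < 2 * support + 1) return(0)
    idx <- (support + 1):(n - support)
    is_peak <- rep(TRUE, length(idx))
    for (j in seq_len(support)) {
      is_peak <- is_peak & x[idx] > x[idx - j] & x[idx] > x[idx + j]
    }
    sum(is_peak)
  }
}

f_quantile <- function(q) {
  force(q)
  function(x, p) unname(stats::quantile(x, q, type = 7))
}

f_fft_magnitude <- function(k) {
  force(k)
  function(x, p) {
    if (k >= p$n) return(NaN)
    Mod(stats::fft(x)[k + 1L])
  }
}

f_c3 <- function(lag) {
  force(lag)
  function(x, p) {
    if (p$n <= 2 * lag) return(NaN)
    i <- seq_len(p$n - 2 * lag)
    mean(x[i + 2 * lag] * x[i + lag] * x[i])
  }
}

f_large_sd <- function(r) {
  force(r)
  function(x, p) as.numeric(p$sd_pop > r * p$range)
}

f_symmetry_looking <- function(r) {
  force(r)
  function(x, p) as.numeric(abs(p$mean - stats::median(x)) < r * p$range)
}

longest_run <- function(b) {
  if (!any(b)) return(0L)
  r <- rle(b)
  max(r$lengths[r$values])
}

core_defs <- function() {
  defs <- list(
    feature_def("mean", "real", function(x, p) p$mean),
    feature_def("median", "real", function(x, p) stats::median(x)),
    feature_def("standard_deviation", "real", function(x, p) p$sd_pop),
    feature_def("variance", "real", function(x, p) p$var_pop),
    feature_def("maximum", "real", function(x, p) p$max),
    feature_def("minimum", "real", function(x, p) p$min),
    feature_def("abs_energy", "real", function(x, p) sum(x^2)),
    feature_def("root_mean_square", "real", function(x, p) sqrt(mean(x^2))),
    feature_def("mean_abs_change", "real",
                function(x, p) if (p$n < 2) NaN else mean(abs(p$diffs))),
    feature_def("mean_change", "real",
                function(x, p) if (p$n < 2) NaN else (x[p$n] - x[1]) / (p$n - 1)),
    feature_def("skewness", "real", function(x, p) {
      if (p$var_pop == 0) return(NaN)
      mean((x - p$mean)^3) / p$var_pop^1.5
    }),
    feature_def("kurtosis", "real", function(x, p) {
      if (p$var_pop == 0) return(NaN)
      mean((x - p$mean)^4) / p$var_pop^2 - 3
    }),
    feature_def("count_above_mean", "real", function(x, p) sum(x > p$mean)),
    feature_def("count_below_mean", "real", function(x, p) sum(x < p$mean)),
    feature_def("longest_strike_above_mean", "real",
                function(x, p) longest_run(x > p$mean)),
    feature_def("first_location_of_maximum", "real",
                function(x, p) (which.max(x) - 1) / p$n),
    feature_def("last_location_of_maximum", "real",
                function(x, p) max(which(x == p$max)) / p$n),
    feature_def("first_location_of_minimum", "real",
                function(x, p) (which.min(x) - 1) / p$n),
    feature_def("last_location_of_minimum", "real",
                function(x, p) max(which(x == p$min)) / p$n),
    feature_def("cid_ce", "real",
                function(x, p) if (p$n < 2) NaN else sqrt(sum(p$diffs^2))),
    feature_def("has_duplicate", "binary",
                function(x, p) as.numeric(anyDuplicated(x) > 0)),
    feature_def("has_duplicate_max", "binary",
                function(x, p) as.numeric(sum(x == p$max) > 1)),
    feature_def("has_duplicate_min", "binary",
                function(x, p) as.numeric(sum(x == p$min) > 1))
  )
  for (l in c(1L, 2L, 5L, 10L)) {
    defs[[length(defs) + 1L]] <-
      feature_def(sprintf("autocorrelation_lag_%d", l), "real",
                  f_autocorrelation(l))
  }
  for (s in c(1L, 3L)) {
    defs[[length(defs) + 1L]] <-
      feature_def(sprintf("number_of_peaks_support_%d", s), "real",
                  f_number_of_peaks(s))
  }
  for (q in c(0.1, 0.25, 0.75, 0.9)) {
    defs[[length(defs) + 1L]] <-
      feature_def(sprintf("quantile_q_%g", q), "real", f_quantile(q))
  }
  for (k in 1:5) {
    defs[[length(defs) + 1L]] <-
      feature_def(sprintf("fft_coefficient_magnitude_k_%d", k), "real",
                  f_fft_magnitude(k))
  }
  defs[[length(defs) + 1L]] <- feature_def("c3_lag_1", "real", f_c3(1L))
  for (r in c(0.25, 0.35)) {
    defs[[length(defs) + 1L]] <-
      feature_def(sprintf("large_standard_deviation_r_%g", r), "binary",
                  f_large_sd(r))
  }
  defs[[length(defs) + 1L]] <-
    feature_def("symmetry_looking_r_0.25", "binary", f_symmetry_looking(0.25))
  defs
}

# extension pool of additional parameterisations, in a fixed deterministic
# order, used to grow the catalogue toward a requested dimensionality
extension_defs <- function() {
  defs <- list()
  for (l in c(3L, 4L, 6:9, 11:300)) {
    defs[[length(defs) + 1L]] <-
      feature_def(sprintf("autocorrelation_lag_%d", l), "real",
                  f_autocorrelation(l))
  }
  for (k in 6:305) {
    defs[[length(defs) + 1L]] <-
      feature_def(sprintf("fft_coefficient_magnitude_k_%d", k), "real",
                  f_fft_magnitude(k))
  }
  for (q in setdiff(round(seq(0.02, 0.98, by = 0.02), 2), c(0.1, 0.25, 0.75, 0.9))) {
    defs[[length(defs) + 1L]] <-
      feature_def(sprintf("quantile_q_%g", q), "real", f_quantile(q))
  }
  for (l in 2:51) {
    defs[[length(defs) + 1L]] <-
      feature_def(sprintf("c3_lag_%d", l), "real", f_c3(l))
  }
  for (s in c(2L, 4:32)) {
    defs[[length(defs) + 1L]] <-
      feature_def(sprintf("number_of_peaks_support_%d", s), "real",
                  f_number_of_peaks(s))
  }
  for (r in setdiff(round(seq(0.05, 1.5, by = 0.05), 2), c(0.25, 0.35))) {
    defs[[length(defs) + 1L]] <-
      feature_def(sprintf("large_standard_deviation_r_%g", r), "binary",
                  f_large_sd(r))
  }
  for (r in setdiff(round(seq(0.05, 1.5, by = 0.05), 2), 0.25)) {
    defs[[length(defs) + 1L]] <-
      feature_def(sprintf("symmetry_looking_r_%g", r), "binary",
                  f_symmetry_looking(r))
  }
  defs
}

#' Build a feature catalogue
#'
#' The core catalogue holds 42 features per series with formulas fixed by
#' this package (see the feature conventions in the package vignette). A
#' larger catalogue, e.g. the 794-dimensional size used by systematic
#' feature-extraction references, is obtained by growing the core with
#' additional parameterisations (more autocorrelation lags, FFT coefficients,
#' quantiles, nonlinearity and dispersion variants) in a fixed order.
#'
#' @param size number of features per series; `NULL` (default) returns the
#'   core catalogue.
#' @return list of class `feature_catalog`; each element has `name`, `kind`
#'   (`"real"` or `"binary"`) and a pure function of one series.
#' @export
feature_catalog <- function(size = NULL) {
  defs <- core_defs()
  if (!is.null(size)) {
    if (size < length(defs)) {
      defs <- defs[seq_len(size)]
    } else if (size > length(defs)) {
      extra <- extension_defs()
      need <- size - length(defs)
      if (need > length(extra)) {
        stop("requested catalogue size exceeds available definitions",
             call. = FALSE)
      }
      defs <- c(defs, extra[seq_len(need)])
    }
  }
  nm <- vapply(defs, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("duplicate feature names in catalogue", call. = FALSE)
  structure(defs, class = "feature_catalog")
}

#' Compute one feature on one series
#'
#' @param definition one element of a [feature_catalog()].
#' @param series non-empty finite numeric vector.
#' @return a scalar; binary features return exactly 0 or 1; undefined cases
#'   return NaN.
#' @export
compute_feature <- function(definition, series) {
  check_series(series)
  v <- definition$fun(series, series_pre(series))
  as.numeric(v)
}

check_series <- function(series) {
  if (!length(series) || !is.numeric(series)) {
    stop("series must be a non-empty numeric vector", call. = FALSE)
  }
  if (any(!is.finite(series))) {
    stop("series contains non-finite values", call. = FALSE)
  }
  invisible(series)
}

# all catalogue features of one series, sharing precomputations
series_features <- function(series, catalog) {
  check_series(series)
  p <- series_pre(series)
  vapply(catalog, function(d) as.numeric(d$fun(series, p)), numeric(1))
}

#' Extract the feature vector of one recording's derived series
#'
#' @param series_set a `derived_series_set` with the full 60 series (from
#'   [preprocess_recording()] or [derive_series()]).
#' @param catalog a [feature_catalog()].
#' @return named numeric vector of length `60 * length(catalog)`; names are
#'   `<series_name>__<feature_name>`. NaN values are retained.
#' @export
extract_features <- function(series_set, catalog = feature_catalog()) {
  expected <- derived_series_names()
  missing <- setdiff(expected, names(series_set))
  if (length(missing)) {
    stop("series set missing series: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  fnames <- vapply(catalog, `[[`, character(1), "name")
  out <- unlist(lapply(expected, function(s) {
    v <- series_features(series_set[[s]], catalog)
    names(v) <- paste(s, fnames, sep = "__")
    v
  }))
  out
}

#' Build the recordings-by-features matrix for a cohort
#'
#' @param series_sets named list of `derived_series_set` objects, one per
#'   recording, in manifest order.
#' @param manifest manifest data.frame covering exactly these recordings
#'   (`recording_id`, `class_label`, ...).
#' @param catalog a [feature_catalog()].
#' @return object of class `feature_matrix`: list with `values` (numeric
#'   matrix, rows = recordings in manifest order), `columns` (data.frame:
#'   `column_id`, `series_name`, `feature_name`, `value_kind`),
#'   `class_labels`, and `flagged` (data.frame marking all-NaN and constant
#'   columns).
#' @export
build_feature_matrix <- function(series_sets, manifest,
                                 catalog = feature_catalog()) {
  if (!setequal(names(series_sets), manifest$recording_id)) {
    stop("recordings and manifest do not match", call. = FALSE)
  }
  series_sets <- series_sets[manifest$recording_id]
  rows <- lapply(series_sets, extract_features, catalog = catalog)
  values <- do.call(rbind, rows)
  rownames(values) <- manifest$recording_id
  fnames <- vapply(catalog, `[[`, character(1), "name")
  kinds <- vapply(catalog, `[[`, character(1), "kind")
  columns <- data.frame(
    column_id = colnames(values),
    series_name = rep(derived_series_names(), each = length(catalog)),
    feature_name = rep(fnames, times = 60),
    value_kind = rep(kinds, times = 60),
    stringsAsFactors = FALSE)
  all_nan <- apply(values, 2, function(v) all(is.nan(v)))
  constant <- apply(values, 2, function(v) {
    v <- v[!is.nan(v)]
    length(v) > 0 && max(v) == min(v)
  })
  structure(list(values = values, columns = columns,
                 class_labels = manifest$class_label,
                 flagged = data.frame(column_id = columns$column_id,
                                      all_nan = all_nan, constant = constant,
                                      stringsAsFactors = FALSE)),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d recordings x %d feature columns (%d flagged constant, %d all-NaN)\n",
              nrow(x$values), ncol(x$values),
              sum(x$flagged$constant), sum(x$flagged$all_nan)))
  invisible(x)
}
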