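# Per-feature relevance testing: Mann-Whitney U for real-valued features,
# two-sided Fisher exact for binary features, Benjamini-Yekutieli FDR control
# within each one-vs-rest binary problem, and intersection into the set of
# features significant for all three class contrasts.

#' Two-sided Mann-Whitney U test p-value
#'
#' Uses the exact null distribution of U when the pooled sample size is at
#' most 12 and there are no ties; otherwise the normal approximation with
#' midrank tie correction and a 0.5 continuity correction. The two-sided
#' p-value is the null probability of a U at least as far from its mean
#' n1*n2/2 as observed. Symmetric in its arguments.
#'
#' @param x,y non-empty numeric samples.
#' @return p-value in (0, 1].
#' @export
mann_whitney_p <- function(x, y) {
  if (!length(x) || !length(y)) stop("empty sample", call. = FALSE)
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  z <- c(x, y)
  r <- rank(z)
  u1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- anyDuplicated(z) > 0
  if (n <= 12 && !ties) {
    if (u1 == mu) return(1)
    u_min <- min(u1, n1 * n2 - u1)
    # U is symmetric about its mean under the null, so the two tails are
    # equal and disjoint when u_min < mu
    return(min(1, 2 * stats::pwilcox(u_min, n1, n2)))
  }
  tab <- table(z)
  tie_term <- sum(tab^3 - tab)
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  if (sigma2 <= 0) return(1)
  zstat <- max(0, abs(u1 - mu) - 0.5) / sqrt(sigma2)
  min(1, 2 * stats::pnorm(-zstat))
}

#' Two-sided Fisher exact test p-value for a 2x2 table
#'
#' Point-probability method: the p-value sums the hypergeometric point
#' probabilities of all tables with the observed margins whose probability
#' does not exceed that of the observed table (up to a 1e-7 relative
#' tolerance for floating-point equality).
#'
#' @param tab 2x2 matrix of nonnegative integer counts.
#' @return p-value in (0, 1].
#' @export
fisher_exact_p <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2))) stop("need a 2x2 table", call. = FALSE)
  if (any(tab < 0) || any(tab != round(tab))) {
    stop("cells must be nonnegative integers", call. = FALSE)
  }
  if (sum(tab) < 1) stop("grand total must be >= 1", call. = FALSE)
  m <- sum(tab[1, ])          # row-1 margin (white balls)
  nn <- sum(tab[2, ])         # row-2 margin
  k <- sum(tab[, 1])          # column-1 margin (draws)
  a <- tab[1, 1]
  support <- max(0, k - nn):min(k, m)
  dens <- stats::dhyper(support, m, nn, k)
  p_obs <- stats::dhyper(a, m, nn, k)
  min(1, sum(dens[dens <= p_obs * (1 + 1e-7)]))
}

#' Benjamini-Yekutieli step-up rejections
#'
#' Controls the false discovery rate at level `q` under arbitrary dependence:
#' with m p-values and c(m) = sum_{i=1..m} 1/i, the procedure rejects the
#' hypotheses with the k* smallest p-values, where k* is the largest k such
#' that p_(k) <= k q / (m c(m)).
#'
#' @param p_values numeric vector of p-values in [0, 1] (no NaN; exclude
#'   untestable features upstream).
#' @param q FDR level in (0, 1).
#' @return logical vector aligned with `p_values`: TRUE = rejected.
#' @export
benjamini_yekutieli <- function(p_values, q = 0.05) {
  if (!is.numeric(q) || length(q) != 1 || q <= 0 || q >= 1) {
    stop("q must be in (0, 1)", call. = FALSE)
  }
  m <- length(p_values)
  if (m == 0) return(logical(0))
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1] with no missing values", call. = FALSE)
  }
  cm <- sum(1 / seq_len(m))
  o <- order(p_values)
  thresh <- seq_len(m) * q / (m * cm)
  ok <- which(p_values[o] <= thresh)
  rej <- logical(m)
  if (length(ok)) rej[o[seq_len(max(ok))]] <- TRUE
  rej
}

#' Test every feature column against one binary class problem
#'
#' Real-valued columns are compared between the positive class and the rest
#' with the Mann-Whitney U test; binary columns with the two-sided Fisher
#' exact test on the 2x2 feature-value by label table. Columns that are
#' constant or entirely NaN (or whose NaN pattern empties one group) are
#' skipped and counted, so the multiplicity m reflects only testable
#' features. Benjamini-Yekutieli is then applied across the problem's full
#' p-vector.
#'
#' @param fm a [build_feature_matrix()] result.
#' @param positive_class the class contrasted against the pooled rest.
#' @param q FDR level.
#' @return data.frame of class `relevance_table` with columns `column_id`,
#'   `series_name`, `feature_name`, `problem`, `test_name`, `p_value`,
#'   `rejected`, `rank`; attributes `m`, `n_skipped_constant`,
#'   `n_skipped_nan`.
#' @export
select_relevant <- function(fm, positive_class, q = 0.05) {
  if (!inherits(fm, "feature_matrix")) stop("not a feature_matrix", call. = FALSE)
  positive_class <- match.arg(positive_class, CLASS_LABELS)
  lab <- fm$class_labels == positive_class
  if (!any(lab) || all(lab)) {
    stop("both label groups must be non-empty for class ", positive_class,
         call. = FALSE)
  }
  vals <- fm$values
  kinds <- fm$columns$value_kind
  n_const <- 0L; n_nan <- 0L
  ids <- character(0); tests <- character(0); ps <- numeric(0)
  for (j in seq_len(ncol(vals))) {
    v <- vals[, j]
    keep <- !is.nan(v)
    if (!any(keep)) { n_nan <- n_nan + 1L; next }
    vj <- v[keep]; lj <- lab[keep]
    if (!any(lj) || all(lj)) { n_nan <- n_nan + 1L; next }
    if (max(vj) == min(vj)) { n_const <- n_const + 1L; next }
    if (kinds[j] == "binary") {
      tab <- matrix(c(sum(vj == 1 & lj), sum(vj == 1 & !lj),
                      sum(vj == 0 & lj), sum(vj == 0 & !lj)),
                    nrow = 2, byrow = TRUE)
      p <- fisher_exact_p(tab)
      tn <- "fisher_exact"
    } else {
      p <- mann_whitney_p(vj[lj], vj[!lj])
      tn <- "mann_whitney_u"
    }
    ids <- c(ids, fm$columns$column_id[j])
    tests <- c(tests, tn)
    ps <- c(ps, p)
  }
  rej <- benjamini_yekutieli(ps, q)
  idx <- match(ids, fm$columns$column_id)
  out <- data.frame(column_id = ids,
                    series_name = fm$columns$series_name[idx],
                    feature_name = fm$columns$feature_name[idx],
                    problem = positive_class, test_name = tests,
                    p_value = ps, rejected = rej,
                    rank = rank(ps, ties.method = "first"),
                    stringsAsFactors = FALSE)
  attr(out, "m") <- length(ps)
  attr(out, "n_skipped_constant") <- n_const
  attr(out, "n_skipped_nan") <- n_nan
  class(out) <- c("relevance_table", "data.frame")
  out
}

#' One-vs-rest decomposition and common significant features
#'
#' Runs [select_relevant()] with each of G0, G1, G2 as the positive class
#' (FDR controlled within each problem separately) and intersects the three
#' significant sets into the common feature set.
#'
#' @param fm a [build_feature_matrix()] result containing all three classes.
#' @param q FDR level per problem.
#' @return list of class `common_feature_set`: `tables` (named list of
#'   relevance tables), `significant` (named list of column-id vectors),
#'   `counts` (named integer vector of per-problem significant counts),
#'   `common` (character vector of column ids significant in all three
#'   problems), `columns` (column metadata for the common features).
#' @export
one_vs_rest_common <- function(fm, q = 0.05) {
  present <- unique(fm$class_labels)
  missing <- setdiff(CLASS_LABELS, present)
  if (length(missing)) {
    stop("missing class(es): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  tables <- lapply(stats::setNames(CLASS_LABELS, CLASS_LABELS),
                   function(cl) select_relevant(fm, cl, q))
  significant <- lapply(tables, function(t) t$column_id[t$rejected])
  common <- Reduce(intersect, significant)
  structure(list(
    tables = tables,
    significant = significant,
    counts = vapply(significant, length, integer(1)),
    common = common,
    columns = fm$columns[match(common, fm$columns$column_id), , drop = FALSE],
    q = q), class = "common_feature_set")
}

#' @export
print.common_feature_set <- function(x, ...) {
  cat(sprintf(
    "<common_feature_set> q = %g; significant per problem: G0 %d, G1 %d, G2 %d; common %d\n",
    x$q, x$counts[["G0"]], x$counts[["G1"]], x$counts[["G2"]],
    length(x$common)))
  invisible(x)
}
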