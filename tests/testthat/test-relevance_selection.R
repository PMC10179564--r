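# Mann-Whitney U, Fisher exact, Benjamini-Yekutieli, one-vs-rest selection.

test_that("Mann-Whitney worked examples hold", {
  # x=[1,2,3] vs y=[4,5,6]: U_min = 0, exact two-sided p = 0.1
  expect_equal(mann_whitney_p(c(1, 2, 3), c(4, 5, 6)), 0.1)
  # identical samples: no separation
  expect_equal(mann_whitney_p(c(1, 2, 3), c(1, 2, 3)), 1, tolerance = 1e-12)
  # symmetry in the two samples
  set.seed(9)
  x <- rnorm(20)
  y <- rnorm(25, 0.5)
  expect_equal(mann_whitney_p(x, y), mann_whitney_p(y, x))
  expect_error(mann_whitney_p(numeric(0), y), "empty")
})

test_that("Mann-Whitney exact branch equals full enumeration for n1+n2 <= 10", {
  # independent oracle: enumerate every assignment of the pooled values
  enum_p <- function(x, y) {
    n1 <- length(x)
    pooled <- c(x, y)
    n <- length(pooled)
    u_stat <- function(idx) {
      xx <- pooled[idx]
      yy <- pooled[-idx]
      sum(outer(xx, yy, ">")) + 0.5 * sum(outer(xx, yy, "=="))
    }
    mu <- n1 * (n - n1) / 2
    obs <- abs(u_stat(seq_len(n1)) - mu)
    combs <- utils::combn(n, n1)
    hits <- sum(apply(combs, 2, function(idx) {
      abs(u_stat(idx) - mu) >= obs - 1e-12
    }))
    hits / ncol(combs)
  }
  set.seed(31)
  for (rep in 1:40) {
    n1 <- sample(1:5, 1)
    n2 <- sample(1:5, 1)
    # continuous draws: no ties, so the exact branch applies
    x <- rnorm(n1)
    y <- rnorm(n2)
    expect_equal(mann_whitney_p(x, y), enum_p(x, y), tolerance = 1e-9,
                 info = sprintf("rep %d (n1=%d n2=%d)", rep, n1, n2))
  }
})

test_that("Mann-Whitney approximation matches stats::wilcox.test with ties", {
  set.seed(77)
  for (rep in 1:20) {
    x <- round(rnorm(30), 1)
    y <- round(rnorm(30, 0.3), 1)
    ref <- suppressWarnings(
      stats::wilcox.test(x, y, correct = TRUE, exact = FALSE)$p.value)
    expect_equal(mann_whitney_p(x, y), ref, tolerance = 1e-9)
  }
})

test_that("Mann-Whitney approximation is close to a permutation oracle", {
  set.seed(1234)
  x <- rnorm(30)
  y <- rnorm(30, 0.8)
  pooled <- c(x, y)
  mu <- 30 * 30 / 2
  u_of <- function(xx, yy) {
    sum(outer(xx, yy, ">")) + 0.5 * sum(outer(xx, yy, "=="))
  }
  obs <- abs(u_of(x, y) - mu)
  hits <- 0L
  n_perm <- 20000L
  for (b in seq_len(n_perm)) {
    idx <- sample.int(60, 30)
    if (abs(u_of(pooled[idx], pooled[-idx]) - mu) >= obs) hits <- hits + 1L
  }
  expect_lt(abs(mann_whitney_p(x, y) - hits / n_perm), 0.01)
})

test_that("Fisher exact worked examples hold", {
  expect_equal(fisher_exact_p(matrix(c(2, 0, 0, 2), 2)), 1 / 3)
  expect_equal(fisher_exact_p(matrix(c(1, 1, 1, 1), 2)), 1)
  expect_equal(fisher_exact_p(matrix(c(5, 0, 0, 5), 2)), 2 / 252)
  expect_error(fisher_exact_p(matrix(c(-1, 0, 0, 2), 2)), "negative")
})

test_that("Fisher exact matches hypergeometric enumeration on random tables", {
  enum_fisher <- function(tab) {
    r1 <- sum(tab[1, ])
    c1 <- sum(tab[, 1])
    n <- sum(tab)
    lo <- max(0, r1 + c1 - n)
    hi <- min(r1, c1)
    probs <- stats::dhyper(lo:hi, c1, n - c1, r1)
    p_obs <- stats::dhyper(tab[1, 1], c1, n - c1, r1)
    sum(probs[probs <= p_obs * (1 + 1e-7)])
  }
  set.seed(404)
  for (rep in 1:200) {
    tab <- matrix(sample(0:10, 4, replace = TRUE), 2)
    if (sum(tab) == 0) next
    expect_equal(fisher_exact_p(tab), enum_fisher(tab), tolerance = 1e-12,
                 info = paste(tab, collapse = ","))
    # cross-check against stats::fisher.test
    if (all(rowSums(tab) > 0) && all(colSums(tab) > 0)) {
      expect_equal(fisher_exact_p(tab), stats::fisher.test(tab)$p.value,
                   tolerance = 1e-7, info = paste(tab, collapse = ","))
    }
  }
})

test_that("Benjamini-Yekutieli worked examples hold", {
  expect_equal(benjamini_yekutieli(0.01, 0.05), TRUE)
  expect_equal(benjamini_yekutieli(c(0.01, 0.02, 0.04), 0.05),
               c(FALSE, FALSE, FALSE))
  expect_equal(benjamini_yekutieli(c(0.001, 0.5, 0.9), 0.05),
               c(TRUE, FALSE, FALSE))
  expect_error(benjamini_yekutieli(c(0.1), 0), "q")
  expect_error(benjamini_yekutieli(c(0.1), 1), "q")
})

test_that("BY is step-up: ranks below k* are rejected even above their own threshold", {
  # m = 2, c(2) = 1.5; thresholds 0.0167, 0.0333
  # p = [0.02, 0.03]: rank 1 exceeds its threshold but rank 2 passes
  rej <- benjamini_yekutieli(c(0.02, 0.03), 0.05)
  expect_equal(rej, c(TRUE, TRUE))
})

test_that("BY matches a brute-force threshold scan and p.adjust on random vectors", {
  brute_by <- function(p, q) {
    m <- length(p)
    cm <- sum(1 / seq_len(m))
    o <- order(p)
    ks <- which(p[o] <= seq_len(m) * q / (m * cm))
    rej <- rep(FALSE, m)
    if (length(ks)) rej[o[seq_len(max(ks))]] <- TRUE
    rej
  }
  set.seed(55)
  for (rep in 1:30) {
    m <- sample(1:1000, 1)
    p <- stats::runif(m)^sample(1:3, 1)  # skew some vectors toward 0
    q <- sample(c(0.01, 0.05, 0.2), 1)
    got <- benjamini_yekutieli(p, q)
    expect_identical(got, brute_by(p, q), info = sprintf("rep %d m=%d", rep, m))
    expect_identical(got, stats::p.adjust(p, "BY") <= q,
                     info = sprintf("p.adjust rep %d", rep))
  }
})

test_that("BY rejections are nested within BH within raw thresholding", {
  set.seed(66)
  for (rep in 1:20) {
    p <- stats::runif(200)^2
    by <- benjamini_yekutieli(p, 0.05)
    bh <- stats::p.adjust(p, "BH") <= 0.05
    raw <- p <= 0.05
    expect_true(all(!by | bh))   # BY subset of BH
    expect_true(all(!bh | raw))  # BH subset of raw
  }
})

test_that("decreasing any single p-value never shrinks the rejection set", {
  set.seed(88)
  p <- stats::runif(40)
  base <- benjamini_yekutieli(p, 0.05)
  for (rep in 1:40) {
    i <- sample.int(40, 1)
    p2 <- p
    p2[i] <- p[i] * stats::runif(1)
    new <- benjamini_yekutieli(p2, 0.05)
    # every feature rejected before (other than i itself) stays rejected
    expect_true(all(new[-i] >= base[-i]),
                info = sprintf("rep %d lowered index %d", rep, i))
    expect_true(new[i] >= base[i])
  }
})

# small feature matrix with known structure for selection tests
selection_fixture <- function(n_per_class = 20, seed = 3) {
  set.seed(seed)
  classes <- rep(c("G0", "G1", "G2"), each = n_per_class)
  n <- length(classes)
  values <- cbind(
    separated = ifelse(classes == "G1", 10, 0) + rnorm(n, 0, 0.1),
    null_real = rnorm(n),
    constant = rep(1, n),
    binary_sep = as.numeric(classes == "G1"),
    binary_null = rep(c(0, 1), length.out = n))
  colnames(values) <- c("FNx__f1", "FNx__f2", "FNvz__f3", "MPHaz__f4",
                        "MPHaz__f5")
  rownames(values) <- sprintf("r%02d", seq_len(n))
  structure(list(
    values = values,
    columns = data.frame(
      column_id = colnames(values),
      series_name = c("FNx", "FNx", "FNvz", "MPHaz", "MPHaz"),
      feature_name = c("f1", "f2", "f3", "f4", "f5"),
      value_kind = c("real", "real", "real", "binary", "binary"),
      stringsAsFactors = FALSE),
    class_labels = classes,
    flagged = data.frame(column_id = colnames(values),
                         all_nan = FALSE,
                         constant = c(FALSE, FALSE, TRUE, FALSE, FALSE),
                         stringsAsFactors = FALSE)),
    class = "feature_matrix")
}

test_that("select_relevant applies the right test per column kind", {
  fm <- selection_fixture()
  tab <- select_relevant(fm, "G1", q = 0.05)
  expect_s3_class(tab, "data.frame")
  expect_setequal(tab$test_name[tab$column_id == "FNx__f1"], "mann_whitney_u")
  expect_setequal(tab$test_name[tab$column_id == "MPHaz__f4"], "fisher_exact")
  # constant column skipped
  expect_false("FNvz__f3" %in% tab$column_id)
  expect_equal(attr(tab, "n_skipped_constant"), 1L)
  expect_equal(nrow(tab), 4L)
  # the separated columns are rejected, the null ones are not
  expect_true(tab$rejected[tab$column_id == "FNx__f1"])
  expect_true(tab$rejected[tab$column_id == "MPHaz__f4"])
  expect_false(tab$rejected[tab$column_id == "FNx__f2"])
  expect_false(tab$rejected[tab$column_id == "MPHaz__f5"])
  expect_true(all(tab$p_value >= 0 & tab$p_value <= 1))
})

test_that("a column identical across classes gets p = 1 and no rejection", {
  fm <- selection_fixture()
  n_cl <- sum(fm$class_labels == "G0")
  fm$values[, "FNx__f2"] <- rep(seq_len(n_cl), 3)  # same values in every class
  tab <- select_relevant(fm, "G0", q = 0.05)
  row <- tab[tab$column_id == "FNx__f2", ]
  expect_gt(row$p_value, 0.9)
  expect_false(row$rejected)
})

test_that("perfect binary separation at n=30/60 is rejected", {
  classes <- rep(c("G0", "G1", "G2"), each = 30)
  values <- matrix(as.numeric(classes == "G0"), ncol = 1,
                   dimnames = list(NULL, "FNx__b"))
  fm <- structure(list(
    values = values,
    columns = data.frame(column_id = "FNx__b", series_name = "FNx",
                         feature_name = "b", value_kind = "binary",
                         stringsAsFactors = FALSE),
    class_labels = classes,
    flagged = data.frame(column_id = "FNx__b", all_nan = FALSE,
                         constant = FALSE, stringsAsFactors = FALSE)),
    class = "feature_matrix")
  tab <- select_relevant(fm, "G0", q = 0.05)
  expect_true(tab$rejected)
  expect_lt(tab$p_value, 1e-20)
})

test_that("select_relevant validates the positive class", {
  fm <- selection_fixture()
  expect_error(select_relevant(fm, "G9"))
  fm$class_labels <- rep("G0", nrow(fm$values))
  expect_error(select_relevant(fm, "G1"), "class|empty")
})

test_that("one_vs_rest_common intersects the three per-problem sets", {
  fm <- selection_fixture()
  res <- one_vs_rest_common(fm, q = 0.05)
  expect_s3_class(res, "common_feature_set")
  expect_named(res$tables, c("G0", "G1", "G2"))
  # separated real + separated binary single out G1, so they are significant
  # in all three one-vs-rest problems (the deviating class shifts every
  # pooled-rest comparison)
  expect_true(all(c("FNx__f1", "MPHaz__f4") %in% res$common))
  expect_false("FNx__f2" %in% res$common)
  # common set is a subset of every per-problem set
  for (cl in c("G0", "G1", "G2")) {
    sig <- res$tables[[cl]]$column_id[res$tables[[cl]]$rejected]
    expect_true(all(res$common %in% sig))
    expect_equal(res$counts[[cl]], length(sig))
  }
})

test_that("one_vs_rest_common requires all three classes", {
  fm <- selection_fixture()
  fm$class_labels[fm$class_labels == "G2"] <- "G1"
  expect_error(one_vs_rest_common(fm), "class")
})

test_that("intersection worked example: {A,B}, {B,C}, {B} -> {B}", {
  expect_equal(Reduce(intersect, list(c("A", "B"), c("B", "C"), "B")), "B")
})
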