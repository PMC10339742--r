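test_that("importance is normalized and concentrates on the driving feature", {
  set.seed(1)
  x <- matrix(rnorm(80 * 5), 80, 5,
              dimnames = list(NULL, paste0("f", 1:5)))
  y <- 3 * x[, 1]
  for (method in c("split_gain", "coverage")) {
    rep_ <- gbm_importance(x, y, method = method, seed = 2)
    expect_equal(sum(rep_$importance), 1, tolerance = 1e-9)
    expect_true(all(rep_$importance >= 0))
    expect_equal(rep_$ranking$descriptor[1], "f1")
  }
  expect_error(gbm_importance(x, rep(1, 80)), "constant")
})

test_that("coverage favours a many-split feature that gain does not", {
  # a binary feature explains most of y in one split (high gain, low cover);
  # a continuous feature carries a weak wiggly signal that the trees chase
  # through many small splits (low gain, high cover)
  set.seed(9)
  n <- 120
  x <- cbind(bin = rep(c(0, 1), each = n / 2), cont = rnorm(n))
  y <- 3 * x[, "bin"] + 0.4 * sin(3 * x[, "cont"])
  gain <- gbm_importance(x, y, method = "split_gain", seed = 1)
  cover <- gbm_importance(x, y, method = "coverage", seed = 1)
  expect_equal(gain$ranking$descriptor[1], "bin")
  expect_equal(cover$ranking$descriptor[1], "cont")
})

test_that("column permutation permutes importances (up to fit jitter)", {
  set.seed(4)
  x <- matrix(rnorm(60 * 6), 60, 6, dimnames = list(NULL, paste0("f", 1:6)))
  y <- 2 * x[, 2] - x[, 5] + rnorm(60, sd = 0.2)
  i1 <- gbm_importance(x, y, seed = 7)$importance
  perm <- c(3, 1, 6, 2, 5, 4)
  i2 <- gbm_importance(x[, perm], y, seed = 7)$importance
  expect_equal(i1[names(i2)], i2, tolerance = 0.02)
  expect_setequal(names(sort(i1, decreasing = TRUE))[1:2], c("f2", "f5"))
})

test_that("cumulative selection applies the prefix rule", {
  rep_ <- structure(list(
    ranking = data.frame(descriptor = c("a", "b", "c", "d"),
                         importance = c(0.5, 0.3, 0.1, 0.1),
                         cumulative = c(0.5, 0.8, 0.9, 1.0)),
    importance = c(a = 0.5, b = 0.3, c = 0.1, d = 0.1),
    method = "split_gain"), class = "importance_report")
  expect_equal(select_cumulative(rep_, 0.85), c("a", "b", "c"))
  expect_equal(select_cumulative(rep_, 1.0), c("a", "b", "c", "d"))
  expect_error(select_cumulative(rep_, 0), "threshold")
  expect_error(select_cumulative(rep_, 1.2), "threshold")
})

test_that("raising the threshold never drops a selected descriptor", {
  set.seed(6)
  x <- matrix(rnorm(60 * 8), 60, 8, dimnames = list(NULL, paste0("f", 1:8)))
  y <- x[, 1] + 0.5 * x[, 2] + rnorm(60, sd = 0.3)
  rep_ <- gbm_importance(x, y, seed = 3)
  prev <- character(0)
  for (thr in c(0.3, 0.5, 0.7, 0.85, 1.0)) {
    cur <- select_cumulative(rep_, thr)
    expect_true(all(prev %in% cur))
    prev <- cur
  }
})

test_that("correlation matrix matches the Pearson formula and flags pairs", {
  x <- cbind(a = c(1, 2, 4), b = c(2, 1, 3), c = c(1, 2, 4))
  pearson <- function(u, v) {
    sum((u - mean(u)) * (v - mean(v))) /
      sqrt(sum((u - mean(u))^2) * sum((v - mean(v))^2))
  }
  expect_warning(cm <- correlation_matrix(x), "r")
  expect_equal(cm["a", "b"], pearson(x[, "a"], x[, "b"]))
  expect_equal(cm["a", "c"], 1)
  flagged <- attr(cm, "flagged")
  expect_true(nrow(flagged) >= 1)
  expect_true(any(flagged$a == "a" & flagged$b == "c"))
})

test_that("zero-variance columns are reported, not NaN-propagated", {
  x <- cbind(a = c(1, 2, 3, 5), z = rep(1, 4))
  cm <- suppressWarnings(correlation_matrix(x, flag_threshold = 0.99))
  expect_equal(attr(cm, "undefined"), "z")
  expect_true(is.na(cm["a", "z"]))
  expect_false(is.na(cm["a", "a"]))
})

test_that("a low-correlation selected set passes the redundancy check", {
  set.seed(12)
  x <- matrix(rnorm(200 * 4), 200, 4,
              dimnames = list(NULL, c("HD", "ME", "HC", "HS")))
  expect_silent(cm <- correlation_matrix(x))
  expect_equal(nrow(attr(cm, "flagged")), 0)
})
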