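test_that("prefilter drops missing, constant and collinear descriptors", {
  set.seed(1)
  n <- 60
  base <- rnorm(n)
  x <- cbind(const = rep(2, n),
             miss = c(NA, rnorm(n - 1)),
             a = base,
             b = base + rnorm(n, sd = 0.1),  # |r| ~ 0.99 with a
             c = rnorm(n))
  y <- base + rnorm(n, sd = 0.3)
  kept <- prefilter(x, y, corr_threshold = 0.8)
  expect_false("const" %in% kept)
  expect_false("miss" %in% kept)
  expect_equal(sum(c("a", "b") %in% kept), 1)  # exactly one of the pair
  expect_true("a" %in% kept)  # a is more correlated with y
  expect_true("c" %in% kept)
  expect_error(prefilter(x, y, corr_threshold = 1.5), "corr_threshold")
})

test_that("prefilter is idempotent", {
  set.seed(2)
  x <- matrix(rnorm(50 * 20), 50, 20)
  x[, 2] <- x[, 1] + rnorm(50, sd = 0.05)
  colnames(x) <- paste0("D", 1:20)
  y <- rnorm(50)
  k1 <- prefilter(x, y)
  k2 <- prefilter(x[, k1], y)
  expect_identical(k1, k2)
})

test_that("descriptors with the published correlation structure all pass", {
  # seven descriptors whose pairwise correlations match the reported matrix
  # (max |r| = 0.66, well under the 0.8 bar)
  R <- diag(7)
  vals <- list(c(0.32, 0.13, 0.09, 0.66, 0.02, 0.54),
               c(0.00, 0.04, 0.58, 0.35, 0.04),
               c(-0.09, 0.12, 0.00, 0.02),
               c(0.13, 0.17, -0.43),
               c(0.47, 0.19),
               c(-0.46))
  for (i in 1:6) for (jj in seq_along(vals[[i]])) {
    R[i, i + jj] <- R[i + jj, i] <- vals[[i]][jj]
  }
  set.seed(31)
  z <- matrix(rnorm(800 * 7), 800, 7) %*% chol(R)
  colnames(z) <- c("FFP", "MTI", "MEE", "RNO", "HDH", "HTZ", "CHZ")
  y <- z %*% rnorm(7)
  expect_setequal(prefilter(z, y, corr_threshold = 0.8), colnames(z))
})

test_that("fit_ols matches the normal-equations oracle", {
  for (s in 1:5) {
    d <- make_linear_data(n = 30, p = 4, noise_sd = 0.5, seed = s)
    fit <- fit_ols(d$x, d$y)
    xm <- cbind(1, d$x)
    oracle <- solve(t(xm) %*% xm, t(xm) %*% d$y)
    expect_lt(max(abs(c(fit$intercept, fit$coefficients) - oracle)), 1e-8)
  }
})

test_that("fit_ols statistics behave at the extremes", {
  d <- make_linear_data(n = 25, p = 3, noise_sd = 0, seed = 4)
  expect_equal(fit_ols(d$x, d$y)$r2, 1, tolerance = 1e-12)
  set.seed(5)
  y_noise <- rnorm(25)
  fit <- fit_ols(d$x, y_noise)
  expect_lt(fit$r2, 0.3)  # near zero for an unrelated response
  x_bad <- cbind(d$x, dup = d$x[, 1])
  expect_error(fit_ols(x_bad, d$y), "dup")
  expect_error(fit_ols(d$x[1:4, ], d$y[1:4]), "more rows")
})

test_that("fisher criterion follows its defining formula", {
  d <- make_linear_data(n = 30, p = 3, noise_sd = 1, seed = 6)
  fit <- fit_ols(d$x, d$y)
  expect_equal(fit$fisher_F,
               (fit$r2 / 3) / ((1 - fit$r2) / (30 - 3 - 1)))
})

test_that("greedy stepwise selection recovers a noiseless linear truth", {
  spec <- synthetic_spec(n_compounds = 50, n_descriptors = 30,
                         n_informative = 4, n_constant = 2,
                         n_collinear_pairs = 2, noise_sd = 0,
                         missing_fraction = 0, seed = 8)
  d <- generate_synthetic(spec)
  kept <- prefilter(d$descriptors, d$activity)
  curve <- stepwise_select(d$descriptors[, kept], d$activity, max_k = 6)
  expect_true(all(diff(curve$summary$r2) >= -1e-10))
  k4 <- which(curve$summary$k == 4)
  expect_setequal(curve$models[[k4]]$descriptors, d$truth$informative)
  expect_lt(max(abs(curve$models[[k4]]$coefficients -
                      d$truth$coefficients[curve$models[[k4]]$descriptors])),
            1e-6)
})

test_that("stepwise clamps an oversized request with a warning", {
  d <- make_linear_data(n = 30, p = 4, noise_sd = 0.2, seed = 9)
  expect_warning(curve <- stepwise_select(d$x, d$y, max_k = 10), "clamp")
  expect_lte(max(curve$summary$k), 4)
})

test_that("plateau rule picks the size before the flat step", {
  fake <- structure(list(
    summary = data.frame(k = 1:4, descriptor_added = letters[1:4],
                         r2 = c(0.4, 0.6, 0.65, 0.66),
                         r2_cv = c(0.3, 0.55, 0.60, 0.603),
                         fisher_F = 1:4),
    models = as.list(1:4)), class = "selection_curve")
  chosen <- choose_model(fake, plateau_delta = 0.01)
  expect_equal(attr(chosen, "k"), 3)

  single <- structure(list(
    summary = fake$summary[1, ], models = fake$models[1]),
    class = "selection_curve")
  expect_equal(attr(choose_model(single), "k"), 1)

  rising <- fake
  rising$summary$r2_cv <- c(0.2, 0.4, 0.6, 0.8)
  expect_warning(ch <- choose_model(rising), "rising")
  expect_equal(attr(ch, "k"), 4)
})

test_that("equation rendering follows the standard layout", {
  m <- structure(list(intercept = 57.74,
                      coefficients = c(FFP = 325.03, MTI = -3.16),
                      r2 = 0.7, r2_cv = 0.6, fisher_F = 10,
                      n_descriptors = 2, n = 44,
                      descriptors = c("FFP", "MTI")),
                 class = "linear_model")
  expect_equal(format_equation(m),
               "-lg(IC50) = 325.03*FFP - 3.16*MTI + 57.74")
})
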