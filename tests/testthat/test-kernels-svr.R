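test_that("mix kernel reduces to its components at the weight limits", {
  set.seed(1)
  x <- rnorm(6); z <- rnorm(6)
  gamma <- 0.7; p <- 3
  rbf_only <- kernel_spec("mix", gamma = gamma, p = p, w = 1, b = 0)
  expect_identical(kernel_eval(rbf_only, x, z),
                   kernel_eval(kernel_spec("rbf", gamma = gamma), x, z))
  poly_only <- kernel_spec("mix", gamma = gamma, p = p, w = 0, b = 0)
  expect_identical(kernel_eval(poly_only, x, z),
                   kernel_eval(kernel_spec("poly", p = p), x, z))
  expect_equal(kernel_eval(kernel_spec("rbf", gamma = 2), x, x), 1)
})

test_that("mix kernel self-evaluation matches the hand expansion", {
  set.seed(2)
  x <- rnorm(5)
  spec <- kernel_spec("mix", gamma = 50.47, p = 2, w = 0.04, b = 0.03)
  n2 <- sum(x^2)
  expect_equal(kernel_eval(spec, x, x),
               0.04 + 0.96 * (n2 + 1)^2 + 0.03 * n2)
})

test_that("kernel parameters are validated", {
  expect_error(kernel_spec("rbf", gamma = 0), "gamma")
  expect_error(kernel_spec("poly", p = 0.5), "p")
  expect_error(kernel_spec("mix", w = 1.2), "w")
  expect_error(kernel_spec("mix", b = -1), "b")
  expect_error(kernel_eval(kernel_spec("rbf"), 1:3, 1:4), "length")
})

test_that("gram matrices are symmetric, PSD for valid mixes, and exact for
           orthonormal rows", {
  set.seed(3)
  x <- matrix(rnorm(10 * 4), 10, 4)
  K <- gram(kernel_spec("mix", gamma = 1, p = 2, w = 0.3, b = 0.5), x)
  expect_lt(max(abs(K - t(K))), 1e-12)
  for (i in 1:100) {
    set.seed(i)
    spec <- kernel_spec("mix", gamma = runif(1, 0.01, 10),
                        p = sample(1:4, 1), w = runif(1), b = runif(1))
    xs <- matrix(rnorm(8 * 3), 8, 3)
    ev <- eigen(gram(spec, xs), symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-8)
  }
  q <- qr.Q(qr(matrix(rnorm(16), 4, 4)))
  expect_equal(gram(kernel_spec("linear"), q), diag(4), tolerance = 1e-12)
  expect_error(gram(kernel_spec("rbf"), x, matrix(0, 2, 5)), "columns")
})

test_that("a wide tube empties the dual solution", {
  K <- diag(3)
  y <- c(0.1, 0.2, 0.15)
  m <- fit_svr(K, y, C = 1, epsilon = 1)
  expect_equal(m$dual_coef, rep(0, 3))
  expect_equal(predict_svr(m, K), rep(m$bias, 3))
  expect_true(m$bias >= max(y) - 1 && m$bias <= min(y) + 1)
})

test_that("KKT structure holds: box bounds and zero coefficients in-tube", {
  set.seed(4)
  x <- matrix(rnorm(30 * 3), 30, 3)
  y <- x[, 1]^2 + rnorm(30, sd = 0.2)
  C <- 5; eps <- 0.1
  K <- gram(kernel_spec("rbf", gamma = 0.8), x)
  m <- fit_svr(K, y, C = C, epsilon = eps)
  expect_true(all(abs(m$dual_coef) <= C + 1e-10))
  resid <- abs(y - m$fitted)
  strictly_inside <- resid < eps - 1e-6
  expect_true(all(abs(m$dual_coef[strictly_inside]) <= 1e-6))
})

test_that("duplicate training points predict identically", {
  set.seed(5)
  x <- matrix(rnorm(10 * 2), 10, 2)
  x[10, ] <- x[1, ]
  y <- rnorm(10); y[10] <- y[1]
  spec <- kernel_spec("rbf", gamma = 1)
  m <- fit_svr(gram(spec, x), y, C = 3, epsilon = 0.05)
  p <- predict_svr(m, gram(spec, x))
  expect_equal(p[1], p[10], tolerance = 1e-8)
})

test_that("predictions are invariant to training-sample order", {
  set.seed(6)
  x <- matrix(rnorm(20 * 3), 20, 3)
  y <- sin(x[, 1]) + rnorm(20, sd = 0.1)
  spec <- kernel_spec("mix", gamma = 1, p = 2, w = 0.5, b = 0.1)
  xnew <- matrix(rnorm(5 * 3), 5, 3)
  f1 <- svr(x, y, kernel = spec, C = 10, epsilon = 0.01, tol = 1e-8)
  perm <- sample(20)
  f2 <- svr(x[perm, ], y[perm], kernel = spec, C = 10, epsilon = 0.01,
            tol = 1e-8)
  expect_equal(predict(f1, xnew), predict(f2, xnew), tolerance = 1e-6)
})

test_that("solution agrees with an independent SVR library on the same
           kernel", {
  set.seed(7)
  x <- matrix(rnorm(25 * 4), 25, 4)
  y <- x[, 1] - 0.5 * x[, 2]^2 + rnorm(25, sd = 0.1)
  gamma <- 0.7; C <- 10; eps <- 0.05
  m1 <- svr(x, y, kernel = kernel_spec("rbf", gamma = gamma), C = C,
            epsilon = eps, scale = FALSE, tol = 1e-9)
  p1 <- predict(m1, x)
  m2 <- e1071::svm(x, y, kernel = "radial", gamma = gamma, cost = C,
                   epsilon = eps, scale = FALSE, tolerance = 1e-8)
  expect_equal(p1, as.numeric(predict(m2, x)), tolerance = 1e-4)
})

test_that("constant activities give constant predictions", {
  set.seed(8)
  x <- matrix(rnorm(12 * 2), 12, 2)
  y <- rep(0.7, 12)
  m <- svr(x, y, kernel = kernel_spec("rbf"), C = 10, epsilon = 0.01)
  expect_equal(predict(m, x), rep(0.7, 12), tolerance = 0.011)
})

test_that("input validation catches malformed problems", {
  expect_error(fit_svr(matrix(1, 2, 3), 1:2), "square")
  expect_error(fit_svr(diag(3), 1:2), "disagree")
  expect_error(fit_svr(diag(2), 1:2, C = -1), "C")
  m <- fit_svr(diag(3), c(1, 2, 3), C = 1, epsilon = 0.1)
  expect_error(predict_svr(m, matrix(1, 2, 2)), "column")
})
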