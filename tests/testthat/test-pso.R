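sphere_dims <- list(pso_dim("a", -5, 5), pso_dim("b", -5, 5),
                    pso_dim("c", -5, 5))

test_that("inertia schedule is linear with exact endpoints", {
  cfg <- pso_config(sphere_dims, ngen = 100, w_init = 0.9, w_end = 0.4)
  expect_identical(inertia(0, cfg), 0.9)
  expect_identical(inertia(100, cfg), 0.4)
  expect_equal(inertia(50, cfg), (0.9 + 0.4) / 2)
  w <- vapply(0:100, inertia, numeric(1), config = cfg)
  expect_lt(max(abs(diff(diff(w)))), 1e-12)  # second differences vanish
  expect_error(inertia(-1, cfg), "gen")
  expect_error(inertia(101, cfg), "gen")
})

test_that("config validation rejects bad swarms", {
  expect_error(pso_config(sphere_dims, swarm_size = 1), "swarm_size")
  expect_error(pso_config(sphere_dims, w_init = 0.3, w_end = 0.5), "w_init")
  expect_error(pso_dim("x", 1, 1), "lower")
})

test_that("a converged swarm at gbest is a fixed point", {
  cfg <- pso_config(sphere_dims, swarm_size = 4, ngen = 10, seed = 1)
  pt <- c(1, -2, 0.5)
  swarm <- list(x = matrix(pt, 4, 3, byrow = TRUE),
                v = matrix(0, 4, 3),
                pbest_x = matrix(pt, 4, 3, byrow = TRUE),
                pbest_f = rep(sum(pt^2), 4),
                gbest_x = pt, gbest_f = sum(pt^2), n_bad = 0)
  out <- pso_step(swarm, function(p) sum(p^2), gen = 1, cfg)
  expect_equal(out$x, swarm$x)
  expect_equal(out$v, swarm$v)
  expect_equal(out$gbest_f, swarm$gbest_f)
})

test_that("zero random factors give pure inertial motion", {
  cfg <- pso_config(sphere_dims, swarm_size = 3, ngen = 10,
                    w_init = 0.8, w_end = 0.8, vmax_frac = 1, seed = 2)
  set.seed(3)
  x <- matrix(runif(9, -2, 2), 3, 3)
  v <- matrix(runif(9, -0.5, 0.5), 3, 3)
  swarm <- list(x = x, v = v, pbest_x = x, pbest_f = rep(Inf, 3),
                gbest_x = x[1, ], gbest_f = Inf, n_bad = 0)
  out <- pso_step(swarm, function(p) sum(p^2), gen = 1, cfg, r1 = 0, r2 = 0)
  expect_equal(out$v, 0.8 * v, tolerance = 1e-12)
  expect_equal(out$x, x + 0.8 * v, tolerance = 1e-12)
})

test_that("global-best trace is monotone and seed-deterministic", {
  cfg <- pso_config(sphere_dims, swarm_size = 12, ngen = 40, seed = 4)
  r1 <- pso_optimize(function(p) sum(p^2), cfg)
  r2 <- pso_optimize(function(p) sum(p^2), cfg)
  expect_identical(r1$trace, r2$trace)
  expect_true(all(diff(r1$trace$gbest_fitness) <= 0))
})

test_that("zero iterations return the best of the initial swarm", {
  cfg <- pso_config(sphere_dims, swarm_size = 10, ngen = 0, seed = 5)
  res <- pso_optimize(function(p) sum(p^2), cfg)
  expect_equal(nrow(res$trace), 1)
  expect_equal(res$value, sum(res$par^2))
})

test_that("non-finite fitness values are quarantined, not propagated", {
  cfg <- pso_config(sphere_dims, swarm_size = 8, ngen = 15, seed = 6)
  spiky <- function(p) if (p[["a"]] > 0) NaN else sum(p^2)
  expect_message(res <- pso_optimize(spiky, cfg), "non-finite")
  expect_true(is.finite(res$value))
})

test_that("integer dimensions are reported as integers within the box", {
  cfg <- pso_config(list(pso_dim("n", 0, 10, "integer"),
                         pso_dim("x", 0, 1)),
                    swarm_size = 15, ngen = 60, seed = 7)
  res <- pso_optimize(function(p) (p[["n"]] - 3)^2 + (p[["x"]] - 0.5)^2, cfg)
  expect_identical(res$par[["n"]], 3)
  expect_lt(abs(res$par[["x"]] - 0.5), 1e-2)
})

test_that("the published mixed-kernel optimum lies inside the default box", {
  dims <- default_search_dims("mix_svr")
  lower <- vapply(dims, `[[`, numeric(1), "lower")
  upper <- vapply(dims, `[[`, numeric(1), "upper")
  opt <- c(C = 206.79, gamma = 50.47, p = 2, w = 0.04, b = 0.03)
  expect_true(all(opt >= lower & opt <= upper))
  dims_rf <- default_search_dims("rf")
  lower_rf <- vapply(dims_rf, `[[`, numeric(1), "lower")
  upper_rf <- vapply(dims_rf, `[[`, numeric(1), "upper")
  opt_rf <- c(NT = 522, MD = 13, MS = 7, ML = 4)
  expect_true(all(opt_rf >= lower_rf & opt_rf <= upper_rf))
})

test_that("tuning returns parameters inside the search box", {
  d <- make_linear_data(n = 30, p = 3, noise_sd = 0.2, seed = 8)
  res <- tune_model("mix_svr", d$x, d$y, n_folds = 3, swarm_size = 6,
                    ngen = 4, seed = 9)
  dims <- default_search_dims("mix_svr")
  for (k in seq_along(dims)) {
    v <- res$par[[dims[[k]]$name]]
    expect_gte(v, dims[[k]]$lower)
    expect_lte(v, dims[[k]]$upper)
  }
  expect_s3_class(res$model, "svr_fit")
  expect_true(is.finite(res$cv_rmse))

  res_rf <- tune_model("rf", d$x, d$y, n_folds = 3, swarm_size = 5,
                       ngen = 3, seed = 10)
  expect_lte(res_rf$par[["ML"]], res_rf$par[["MS"]])
  expect_s3_class(res_rf$model, "rf_fit")
})
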