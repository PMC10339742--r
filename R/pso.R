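#' Define one search dimension for the particle swarm
#'
#' @param name Dimension (hyperparameter) name.
#' @param lower,upper Finite box bounds, `lower < upper`.
#' @param kind `"real"` or `"integer"`. Integer dimensions are carried as
#'   reals by the swarm and rounded to the nearest integer whenever the
#'   fitness is evaluated and when the optimum is reported (the stored
#'   positions stay real, so the dynamics are untouched).
#' @return A list describing the dimension.
#' @export
pso_dim <- function(name, lower, upper, kind = c("real", "integer")) {
  kind <- match.arg(kind)
  if (!is.finite(lower) || !is.finite(upper) || lower >= upper) {
    stop("bounds must be finite with lower < upper")
  }
  list(name = name, lower = lower, upper = upper, kind = kind)
}

#' Particle swarm configuration
#'
#' Global-best PSO with a linearly decreasing inertia weight
#' `w(gen) = (w_init - w_end) * (NGEN - gen) / NGEN + w_end`:
#' large inertia early for wide exploration, small inertia late for local
#' refinement. Velocities are clamped to `vmax_frac` of each dimension's box
#' width; positions are clamped to the box with the offending velocity
#' component zeroed.
#'
#' @param dims List of [pso_dim()] entries.
#' @param swarm_size Number of particles, >= 2.
#' @param ngen Total number of iterations `NGEN`.
#' @param c1,c2 Cognitive and social acceleration coefficients.
#' @param w_init,w_end Inertia schedule endpoints, `w_init >= w_end`.
#' @param vmax_frac Velocity clamp as a fraction of the box width.
#' @param seed Integer seed.
#' @return A list of class `pso_config`.
#' @export
pso_config <- function(dims, swarm_size = 30, ngen = 100, c1 = 2, c2 = 2,
                       w_init = 0.9, w_end = 0.4, vmax_frac = 0.2, seed = 1) {
  if (swarm_size < 2) stop("swarm_size must be >= 2")
  if (w_init < w_end) stop("w_init must be >= w_end")
  if (c1 <= 0 || c2 <= 0) stop("C1 and C2 must be positive")
  structure(list(
    dims = dims, swarm_size = as.integer(swarm_size), ngen = as.integer(ngen),
    c1 = c1, c2 = c2, w_init = w_init, w_end = w_end,
    vmax_frac = vmax_frac, seed = as.integer(seed),
    lower = vapply(dims, `[[`, numeric(1), "lower"),
    upper = vapply(dims, `[[`, numeric(1), "upper"),
    integer_dims = vapply(dims, function(d) d$kind == "integer", logical(1)),
    names = vapply(dims, `[[`, character(1), "name")
  ), class = "pso_config")
}

#' Linearly decreasing inertia weight
#'
#' `w(gen) = (w_init - w_end) * (NGEN - gen) / NGEN + w_end`, so
#' `w(0) = w_init` and `w(NGEN) = w_end`.
#'
#' @param gen Current iteration, in `[0, NGEN]`.
#' @param config A [pso_config()].
#' @return The inertia weight.
#' @export
inertia <- function(gen, config) {
  stopifnot(inherits(config, "pso_config"))
  if (gen < 0 || gen > config$ngen) {
    stop("gen must lie in [0, NGEN]")
  }
  (config$w_init - config$w_end) * (config$ngen - gen) / config$ngen +
    config$w_end
}

# round integer dimensions for fitness evaluation / reporting
round_integer_dims <- function(pos, config) {
  if (any(config$integer_dims)) {
    if (is.matrix(pos)) {
      pos[, config$integer_dims] <- round(pos[, config$integer_dims])
    } else {
      pos[config$integer_dims] <- round(pos[config$integer_dims])
    }
  }
  pos
}

evaluate_swarm <- function(fitness, x, config) {
  xe <- round_integer_dims(x, config)
  vapply(seq_len(nrow(xe)), function(i) {
    val <- tryCatch(fitness(stats::setNames(xe[i, ], config$names)),
                    error = function(e) Inf)
    if (!is.finite(val)) Inf else val
  }, numeric(1))
}

#' Initialize a particle swarm
#'
#' Positions uniform in the box, velocities uniform within the clamp;
#' personal and global bests set from the initial fitness evaluation.
#'
#' @param fitness Function mapping a named position vector to a scalar
#'   (minimized). Non-finite values are treated as `+Inf`.
#' @param config A [pso_config()]. The caller is responsible for seeding
#'   (see [pso_optimize()]).
#' @return A swarm state list (`x`, `v`, `pbest_x`, `pbest_f`, `gbest_x`,
#'   `gbest_f`, `n_bad` count of non-finite evaluations).
#' @export
pso_init <- function(fitness, config) {
  s <- config$swarm_size; d <- length(config$dims)
  width <- config$upper - config$lower
  x <- matrix(stats::runif(s * d), s, d)
  x <- sweep(sweep(x, 2, width, "*"), 2, config$lower, "+")
  vmax <- config$vmax_frac * width
  v <- matrix(stats::runif(s * d, -1, 1), s, d)
  v <- sweep(v, 2, vmax, "*")
  f <- evaluate_swarm(fitness, x, config)
  g <- which.min(f)
  list(x = x, v = v, pbest_x = x, pbest_f = f,
       gbest_x = x[g, ], gbest_f = f[g], n_bad = sum(is.infinite(f)))
}

#' Advance the swarm by one iteration
#'
#' Velocity update `v <- w*v + c1*r1*(pbest - x) + c2*r2*(gbest - x)`,
#' position update `x <- x + v`, with velocity clamping, box clamping
#' (zeroing the clamped component's velocity), fitness evaluation (integer
#' dimensions rounded), and pbest/gbest bookkeeping.
#'
#' @param swarm State from [pso_init()] or a previous step.
#' @param fitness Objective (minimized).
#' @param gen Current iteration (drives the inertia schedule).
#' @param config A [pso_config()].
#' @param r1,r2 Optional random factors (matrices recycled to swarm x dims);
#'   `NULL` (default) draws `U(0,1)` per particle and dimension. Supplying
#'   them makes the step deterministic.
#' @return The updated swarm state.
#' @export
pso_step <- function(swarm, fitness, gen, config, r1 = NULL, r2 = NULL) {
  s <- config$swarm_size; d <- length(config$dims)
  w <- inertia(gen, config)
  if (is.null(r1)) r1 <- matrix(stats::runif(s * d), s, d)
  if (is.null(r2)) r2 <- matrix(stats::runif(s * d), s, d)
  r1 <- matrix(r1, s, d); r2 <- matrix(r2, s, d)
  gb <- matrix(swarm$gbest_x, s, d, byrow = TRUE)

  v <- w * swarm$v + config$c1 * r1 * (swarm$pbest_x - swarm$x) +
    config$c2 * r2 * (gb - swarm$x)
  vmax <- matrix(config$vmax_frac * (config$upper - config$lower),
                 s, d, byrow = TRUE)
  v <- pmin(pmax(v, -vmax), vmax)
  x <- swarm$x + v

  lower <- matrix(config$lower, s, d, byrow = TRUE)
  upper <- matrix(config$upper, s, d, byrow = TRUE)
  out <- x < lower | x > upper
  x <- pmin(pmax(x, lower), upper)
  v[out] <- 0

  f <- evaluate_swarm(fitness, x, config)
  improved <- f < swarm$pbest_f
  pbest_x <- swarm$pbest_x; pbest_x[improved, ] <- x[improved, ]
  pbest_f <- ifelse(improved, f, swarm$pbest_f)
  g <- which.min(pbest_f)
  gbest_f <- pbest_f[g]; gbest_x <- pbest_x[g, ]
  if (gbest_f > swarm$gbest_f) {  # guard: never lose the incumbent
    gbest_f <- swarm$gbest_f; gbest_x <- swarm$gbest_x
  }
  list(x = x, v = v, pbest_x = pbest_x, pbest_f = pbest_f,
       gbest_x = gbest_x, gbest_f = gbest_f,
       n_bad = swarm$n_bad + sum(is.infinite(f)))
}

#' Run the particle swarm optimizer
#'
#' Minimizes `fitness` over the configured box for `NGEN` iterations and
#' returns the best-ever position (integer dimensions reported as integers),
#' its fitness, and the per-iteration global-best trace (monotone
#' non-increasing by construction). `ngen = 0` returns the best of the
#' initial swarm.
#'
#' @param fitness Function from a named position vector to a scalar.
#' @param config A [pso_config()].
#' @return List with `par` (named vector), `value`, `trace` (data frame
#'   `gen`, `gbest_fitness`), and `n_bad` (count of non-finite evaluations,
#'   each treated as `+Inf`).
#' @export
pso_optimize <- function(fitness, config) {
  stopifnot(inherits(config, "pso_config"))
  with_seed(config$seed, {
    swarm <- pso_init(fitness, config)
    trace <- numeric(config$ngen + 1)
    trace[1] <- swarm$gbest_f
    gen <- 0
    while (gen < config$ngen) {
      gen <- gen + 1
      swarm <- pso_step(swarm, fitness, gen, config)
      trace[gen + 1] <- swarm$gbest_f
    }
    par <- round_integer_dims(swarm$gbest_x, config)
    par <- stats::setNames(par, config$names)
    if (any(config$integer_dims)) {
      par[config$integer_dims] <- as.integer(round(par[config$integer_dims]))
    }
    if (swarm$n_bad > 0) {
      message("PSO: ", swarm$n_bad,
              " non-finite fitness evaluation(s) treated as +Inf")
    }
    list(par = par, value = swarm$gbest_f,
         trace = data.frame(gen = 0:config$ngen, gbest_fitness = trace),
         n_bad = swarm$n_bad)
  })
}

#' Default hyperparameter search boxes
#'
#' The boxes the tuner searches: for the mixed-kernel SVR, `C` in
#' `[0.1, 1000]`, `gamma` in `[0.001, 100]`, degree `p` in `{1..5}`,
#' mix weights `w`, `b` in `[0, 1]`; for the random forest, `NT` in
#' `{10..1000}`, `MD` in `{1..30}`, `MS` in `{2..20}`, `ML` in `{1..10}`.
#'
#' @param family `"mix_svr"` or `"rf"`.
#' @return List of [pso_dim()] entries.
#' @export
default_search_dims <- function(family = c("mix_svr", "rf")) {
  family <- match.arg(family)
  if (family == "mix_svr") {
    list(pso_dim("C", 0.1, 1000, "real"),
         pso_dim("gamma", 1e-3, 100, "real"),
         pso_dim("p", 1, 5, "integer"),
         pso_dim("w", 0, 1, "real"),
         pso_dim("b", 0, 1, "real"))
  } else {
    list(pso_dim("NT", 10, 1000, "integer"),
         pso_dim("MD", 1, 30, "integer"),
         pso_dim("MS", 2, 20, "integer"),
         pso_dim("ML", 1, 10, "integer"))
  }
}

# seeded k-fold assignment, sizes as equal as possible
make_folds <- function(n, k, seed) {
  if (k < 2 || k > n) stop("need 2 <= k <= n folds")
  with_seed(seed, sample(rep(seq_len(k), length.out = n)))
}

cv_rmse <- function(fit_predict, x, y, folds) {
  pred <- rep(NA_real_, length(y))
  for (f in sort(unique(folds))) {
    te <- folds == f
    if (sum(te) == length(y) || sum(!te) < 3) stop("degenerate CV fold")
    pred[te] <- fit_predict(x[!te, , drop = FALSE], y[!te],
                            x[te, , drop = FALSE])
  }
  rmse(y, pred)
}

#' Tune model hyperparameters with the particle swarm
#'
#' Minimizes k-fold cross-validated RMSE over the hyperparameter box of the
#' chosen model family. For `"mix_svr"` the dimensions are
#' `C, gamma, p, w, b` (mixed real/integer); for `"rf"` they are
#' `NT, MD, MS, ML` (all integer; `ML` is clamped to `MS` at evaluation so
#' the leaf constraint always holds). Descriptor scaling for the SVR is
#' refitted inside every training fold. The winning configuration is
#' refitted on the full data.
#'
#' @param family `"mix_svr"` or `"rf"`.
#' @param x Descriptor matrix.
#' @param y Activity vector.
#' @param n_folds Number of CV folds (default 5).
#' @param epsilon SVR tube width held fixed during tuning.
#' @param dims Search box; default [default_search_dims()].
#' @param swarm_size,ngen,seed Passed to [pso_config()].
#' @param ... Further [pso_config()] arguments.
#' @return List with `par`, `cv_rmse`, `trace`, and `model` (the refit on
#'   all data: an `svr_fit` or `rf_fit`).
#' @export
tune_model <- function(family = c("mix_svr", "rf"), x, y, n_folds = 5,
                       epsilon = 0.01, dims = default_search_dims(family),
                       swarm_size = 15, ngen = 25, seed = 1, ...) {
  family <- match.arg(family)
  x <- as.matrix(x)
  folds <- make_folds(length(y), n_folds, stage_seed(seed, 1))
  if (family == "mix_svr") {
    fitness <- function(par) {
      ks <- kernel_spec("mix", gamma = par[["gamma"]], p = par[["p"]],
                        w = par[["w"]], b = par[["b"]])
      cv_rmse(function(xtr, ytr, xte) {
        fit <- svr(xtr, ytr, kernel = ks, C = par[["C"]], epsilon = epsilon)
        predict(fit, xte)
      }, x, y, folds)
    }
  } else {
    fitness <- function(par) {
      ml <- min(par[["ML"]], par[["MS"]])
      cfg <- rf_config(NT = par[["NT"]], MD = par[["MD"]], MS = par[["MS"]],
                       ML = ml, seed = stage_seed(seed, 2))
      cv_rmse(function(xtr, ytr, xte) {
        predict_rf(fit_rf(xtr, ytr, cfg), xte)
      }, x, y, folds)
    }
  }
  cfg <- pso_config(dims, swarm_size = swarm_size, ngen = ngen,
                    seed = stage_seed(seed, 3), ...)
  res <- pso_optimize(fitness, cfg)
  par <- res$par
  model <- if (family == "mix_svr") {
    ks <- kernel_spec("mix", gamma = par[["gamma"]], p = par[["p"]],
                      w = par[["w"]], b = par[["b"]])
    svr(x, y, kernel = ks, C = par[["C"]], epsilon = epsilon)
  } else {
    ml <- min(par[["ML"]], par[["MS"]])
    par[["ML"]] <- ml
    fit_rf(x, y, rf_config(NT = par[["NT"]], MD = par[["MD"]],
                           MS = par[["MS"]], ML = ml,
                           seed = stage_seed(seed, 2)))
  }
  list(par = par, cv_rmse = res$value, trace = res$trace, model = model,
       family = family)
}

#' Write a PSO fitness trace to CSV
#' @param trace Data frame from [pso_optimize()].
#' @param path Output CSV path.
#' @export
write_pso_trace <- function(trace, path) {
  utils::write.csv(trace, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
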