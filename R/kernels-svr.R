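#' Specify a kernel
#'
#' Kernel families: `"linear"` `<x,z>`; `"poly"` `(<x,z> + 1)^p`
#' (inhomogeneous); `"rbf"` `exp(-gamma ||x - z||^2)`; and the composite
#' `"mix"` kernel
#' `w * rbf + (1 - w) * poly + b * linear`,
#' a convex combination of the RBF and polynomial kernels plus a conic
#' linear term. With `w` in `[0, 1]` and `b >= 0` the mix is a sum of
#' positive-semidefinite kernels scaled by non-negative weights and is
#' therefore itself a valid (PSD) kernel. The RBF term is strong at fitting,
#' the polynomial and linear terms at generalizing; the mix trades the two
#' off through `w` and `b`.
#'
#' @param family One of `"linear"`, `"poly"`, `"rbf"`, `"mix"`.
#' @param gamma RBF width (> 0); applies to the RBF term of the mix.
#' @param p Polynomial degree (integer >= 1).
#' @param w RBF weight of the mix, in `[0, 1]`.
#' @param b Linear-term weight of the mix, `>= 0`.
#' @return An object of class `kernel_spec`.
#' @export
kernel_spec <- function(family = c("mix", "linear", "poly", "rbf"),
                        gamma = 1, p = 2L, w = 0.5, b = 0.1) {
  family <- match.arg(family)
  if (gamma <= 0) stop("gamma must be positive")
  if (p < 1 || p != round(p)) stop("p must be an integer >= 1")
  if (w < 0 || w > 1) stop("w must lie in [0, 1]")
  if (b < 0) stop("b must be >= 0")
  structure(list(family = family, gamma = gamma, p = as.integer(round(p)),
                 w = w, b = b), class = "kernel_spec")
}

#' Evaluate a kernel on a pair of vectors
#' @param spec A [kernel_spec()].
#' @param x,z Numeric vectors of equal length.
#' @return The scalar kernel value.
#' @export
kernel_eval <- function(spec, x, z) {
  stopifnot(inherits(spec, "kernel_spec"))
  if (length(x) != length(z)) stop("x and z must have equal length")
  drop(gram(spec, matrix(x, 1), matrix(z, 1)))
}

#' Kernel (Gram) matrix
#'
#' Evaluates the kernel on all row pairs of `x` (and `z` when given, yielding
#' the rectangular cross-kernel with rows indexed by `x` and columns by `z`).
#' For valid mix weights the square Gram matrix is positive semidefinite.
#'
#' @param spec A [kernel_spec()].
#' @param x Numeric matrix, samples in rows.
#' @param z Optional second matrix with the same number of columns.
#' @return `nrow(x) x nrow(z)` kernel matrix (symmetric when `z` is absent).
#' @export
gram <- function(spec, x, z = NULL) {
  stopifnot(inherits(spec, "kernel_spec"))
  x <- as.matrix(x)
  sym <- is.null(z)
  z <- if (sym) x else as.matrix(z)
  if (ncol(x) != ncol(z)) stop("x and z must have the same number of columns")
  ip <- tcrossprod(x, z)
  k_lin <- function() ip
  k_poly <- function() (ip + 1)^spec$p
  k_rbf <- function() {
    d2 <- outer(rowSums(x^2), rowSums(z^2), "+") - 2 * ip
    d2[d2 < 0] <- 0
    exp(-spec$gamma * d2)
  }
  K <- switch(spec$family,
    linear = k_lin(),
    poly = k_poly(),
    rbf = k_rbf(),
    mix = spec$w * k_rbf() + (1 - spec$w) * k_poly() + spec$b * k_lin()
  )
  if (sym) K <- (K + t(K)) / 2
  K
}

#' Fit an epsilon-SVR on a precomputed kernel matrix
#'
#' Solves the standard epsilon-insensitive support vector regression dual —
#' box constraints `0 <= alpha_i, alpha*_i <= C`, equality
#' `sum(alpha - alpha*) = 0` — by sequential minimal optimization on the net
#' coefficients `beta = alpha - alpha*`, selecting the maximal-violating
#' pair at each iteration and solving the pair subproblem exactly. The bias
#' is the KKT equality multiplier (midpoint of its admissible interval,
#' which for free support vectors collapses to the usual average).
#'
#' @param K Square positive-semidefinite kernel matrix of the training set.
#' @param y Training activities.
#' @param C Penalty (box) parameter, > 0.
#' @param epsilon Insensitive-tube half-width, >= 0.
#' @param tol KKT violation tolerance for convergence.
#' @param max_iter Iteration cap.
#' @return An object of class `svr_model`: `dual_coef` (`alpha - alpha*` per
#'   training point), `bias`, `objective` (minimized dual), `support`
#'   (indices with nonzero dual coefficient), `C`, `epsilon`, `fitted`,
#'   convergence info.
#' @export
fit_svr <- function(K, y, C = 100, epsilon = 0.01, tol = 1e-6,
                    max_iter = 200000) {
  K <- as.matrix(K)
  if (nrow(K) != ncol(K)) stop("K must be square")
  if (nrow(K) != length(y)) stop("K and y sizes disagree")
  if (C <= 0) stop("C must be positive")
  if (epsilon < 0) stop("epsilon must be >= 0")
  sol <- .smo_svr(K, as.numeric(y), C, epsilon, tol, as.integer(max_iter))
  if (!sol$converged) {
    # a numerical stall with a residual violation far below the activity
    # spread perturbs the bias by a negligible amount; only genuine
    # non-convergence is fatal
    span <- diff(range(y))
    if (sol$violation > max(1e-3 * max(1, span), 1e-5)) {
      stop("SVR solver failed to converge; residual KKT violation ",
           format(sol$violation))
    }
  }
  fitted <- as.numeric(K %*% sol$beta + sol$bias)
  structure(list(
    dual_coef = sol$beta, bias = sol$bias, objective = sol$objective,
    support = which(abs(sol$beta) > 1e-10), C = C, epsilon = epsilon,
    fitted = fitted, iterations = sol$iterations, converged = sol$converged,
    kkt_violation = sol$violation
  ), class = "svr_model")
}

#' Predict from a fitted SVR given a cross-kernel matrix
#'
#' `f(x) = sum_i (alpha_i - alpha*_i) k(x_i, x) + bias`, i.e.
#' `K_test %*% dual_coef + bias`, with `K_test` rows indexed by new samples
#' and columns by training points.
#'
#' @param model An `svr_model` from [fit_svr()].
#' @param K_test Cross-kernel matrix, `n_new x n_train`.
#' @return Numeric vector of predictions.
#' @export
predict_svr <- function(model, K_test) {
  stopifnot(inherits(model, "svr_model"))
  K_test <- as.matrix(K_test)
  if (ncol(K_test) != length(model$dual_coef)) {
    stop("K_test must have one column per training point")
  }
  as.numeric(K_test %*% model$dual_coef + model$bias)
}

#' Fit an SVR on raw descriptors (kernel + scaling handled internally)
#'
#' Convenience wrapper around [fit_svr()]: fits a min-max scaler on the
#' training descriptors, computes the Gram matrix for the requested kernel,
#' and trains the machine. Prediction scales new data with the stored
#' training scaler — the idiom needed for leakage-free cross-validation.
#'
#' @param x Training descriptor matrix.
#' @param y Training activities.
#' @param kernel A [kernel_spec()].
#' @param C,epsilon SVR penalty and tube width.
#' @param scale Scale descriptors to `[0, 1]` first (default TRUE).
#' @param ... Passed to [fit_svr()].
#' @return Object of class `svr_fit` wrapping the `svr_model`, the kernel
#'   spec, the scaler and the training matrix.
#' @export
svr <- function(x, y, kernel = kernel_spec("rbf"), C = 100, epsilon = 0.01,
                scale = TRUE, ...) {
  x <- as.matrix(x)
  scaler <- if (scale) fit_scaler(x, "minmax") else NULL
  xs <- if (scale) scaler_apply(scaler, x) else x
  K <- gram(kernel, xs)
  model <- fit_svr(K, y, C = C, epsilon = epsilon, ...)
  structure(list(model = model, kernel = kernel, scaler = scaler,
                 x_train = xs), class = "svr_fit")
}

#' @param object An `svr_fit`.
#' @param newdata Descriptor matrix for new compounds.
#' @param ... Unused.
#' @rdname svr
#' @export
predict.svr_fit <- function(object, newdata, ...) {
  nd <- as.matrix(newdata)
  if (!is.null(object$scaler)) nd <- scaler_apply(object$scaler, nd)
  predict_svr(object$model, gram(object$kernel, nd, object$x_train))
}

#' Serialize an SVR fit to JSON
#' @param fit An `svr_fit`.
#' @param path Output path.
#' @export
svr_to_json <- function(fit, path) {
  stopifnot(inherits(fit, "svr_fit"))
  obj <- list(
    kernel = unclass(fit$kernel),
    scaler = if (is.null(fit$scaler)) NULL else unclass(fit$scaler),
    dual_coef = fit$model$dual_coef, bias = fit$model$bias,
    C = fit$model$C, epsilon = fit$model$epsilon,
    x_train = fit$x_train
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
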