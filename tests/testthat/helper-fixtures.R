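# small deterministic datasets used across test files

# plain linear data with known coefficients, unit-scale columns
make_linear_data <- function(n = 40, p = 5, beta = NULL, noise_sd = 0,
                             seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("d", seq_len(p))))
  if (is.null(beta)) beta <- c(rep(1, min(3, p)), rep(0, max(0, p - 3)))
  y <- as.numeric(x %*% beta) + rnorm(n, sd = noise_sd)
  list(x = x, y = y, beta = beta)
}

# OLS prediction factory for loocv()
ols_factory <- function(xtr, ytr) {
  fit <- fit_ols(xtr, ytr)
  function(xte) predict(fit, xte)
}

# mean-only prediction factory for loocv()
mean_factory <- function(xtr, ytr) {
  m <- mean(ytr)
  function(xte) rep(m, nrow(as.matrix(xte)))
}

svr_factory <- function(kernel, C = 100, epsilon = 0.01) {
  function(xtr, ytr) {
    fit <- svr(xtr, ytr, kernel = kernel, C = C, epsilon = epsilon)
    function(xte) predict(fit, xte)
  }
}

# dual objective of an epsilon-SVR solution in net coefficients
svr_dual_objective <- function(K, y, beta, epsilon) {
  0.5 * sum(beta * (K %*% beta)) - sum(y * beta) + epsilon * sum(abs(beta))
}

# generic QP reference for the epsilon-SVR dual (kernlab interior-point
# solver on the (alpha, alpha*) formulation)
qp_reference_svr <- function(K, y, C, epsilon) {
  n <- length(y)
  H <- rbind(cbind(K, -K), cbind(-K, K))
  cc <- c(epsilon - y, epsilon + y)
  A <- matrix(c(rep(1, n), rep(-1, n)), 1)
  sol <- kernlab::ipop(cc, H, A, 0, rep(0, 2 * n), rep(C, 2 * n), 0,
                       sigf = 9, maxiter = 400)
  z <- kernlab::primal(sol)
  z[1:n] - z[(n + 1):(2 * n)]
}
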