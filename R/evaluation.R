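#' Coefficient of determination
#'
#' `R^2 = 1 - SS_res / SS_tot`: 1 for perfect prediction, 0 for predicting
#' the mean, negative for worse than the mean.
#'
#' @param y_true Observed values (must not be constant).
#' @param y_pred Predicted values, same length.
#' @return The coefficient of determination.
#' @export
r_squared <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  if (length(y_true) < 2) stop("need at least two observations")
  sst <- sum((y_true - mean(y_true))^2)
  if (sst == 0) stop("y_true is constant; R^2 undefined")
  1 - sum((y_true - y_pred)^2) / sst
}

#' Root mean squared error
#' @param y_true,y_pred Equal-length numeric vectors.
#' @return `sqrt(mean((y_true - y_pred)^2))`.
#' @export
rmse <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  if (length(y_true) == 0) stop("empty input")
  sqrt(mean((y_true - y_pred)^2))
}

#' Leave-one-out cross-validation
#'
#' Predicts every sample from a model trained on the other `n - 1` samples
#' and pools the held-out predictions into the cross-validated coefficient
#' of determination `Rcv^2` (the Q^2 form: `r_squared` of the pooled
#' predictions). The factory retrains from scratch in every fold, so any
#' internal preprocessing (e.g. descriptor scaling) is refitted per fold and
#' no information leaks from the held-out compound.
#'
#' @param model_factory Function `(x_train, y_train)` returning a prediction
#'   function `(x_new) -> numeric`.
#' @param x Descriptor matrix.
#' @param y Activity vector, `length(y) >= 3`.
#' @return List with `predictions` (pooled LOO predictions in input order)
#'   and `r2_cv`.
#' @export
loocv <- function(model_factory, x, y) {
  x <- as.matrix(x)
  n <- length(y)
  if (n < 3) stop("LOOCV needs at least 3 samples")
  if (nrow(x) != n) stop("x and y sizes disagree")
  pred <- numeric(n)
  for (i in seq_len(n)) {
    f <- tryCatch(model_factory(x[-i, , drop = FALSE], y[-i]),
                  error = function(e) {
                    stop("model factory failed in fold ", i, ": ",
                         conditionMessage(e))
                  })
    pred[i] <- f(x[i, , drop = FALSE])
  }
  list(predictions = pred, r2_cv = r_squared(y, pred))
}

# factories for the six standard models -------------------------------------

model_factory <- function(name, kernel_params = list(), C = 100,
                          epsilon = 0.01, rf = rf_config()) {
  kp <- utils::modifyList(list(gamma = 1, p = 2L, w = 0.5, b = 0.1),
                          kernel_params)
  spec_for <- function(fam) switch(fam,
    `svr-linear` = kernel_spec("linear"),
    `svr-poly` = kernel_spec("poly", p = kp$p),
    `svr-rbf` = kernel_spec("rbf", gamma = kp$gamma),
    `svr-mix` = kernel_spec("mix", gamma = kp$gamma, p = kp$p,
                            w = kp$w, b = kp$b))
  switch(name,
    linear = function(xtr, ytr) {
      fit <- fit_ols(xtr, ytr)
      function(xte) predict(fit, xte)
    },
    rf = function(xtr, ytr) {
      fit <- fit_rf(xtr, ytr, rf)
      function(xte) predict_rf(fit, xte)
    },
    `svr-linear` = , `svr-poly` = , `svr-rbf` = , `svr-mix` = {
      ks <- spec_for(name)
      function(xtr, ytr) {
        fit <- svr(xtr, ytr, kernel = ks, C = C, epsilon = epsilon)
        function(xte) predict(fit, xte)
      }
    },
    stop("unknown model: ", name)
  )
}

#' Fit and compare the standard model panel
#'
#' Trains each requested model on the training compounds, evaluates on the
#' training and test sets, and reports the LOOCV `Rcv^2` over the training
#' set — one row per model, mirroring the usual QSAR comparison table
#' (linear, mixed-kernel SVR, RBF/poly/linear SVR, random forest). Also
#' returns the per-compound experimental vs calculated activities of every
#' model.
#'
#' @param x Descriptor matrix (all compounds).
#' @param y Activity vector (all compounds).
#' @param split List with `train_ids` and `test_ids` (see [random_split()]);
#'   ids must match `rownames(x)`.
#' @param models Character vector of model names among `"linear"`, `"rf"`,
#'   `"svr-linear"`, `"svr-poly"`, `"svr-rbf"`, `"svr-mix"`.
#' @param kernel_params Named list overriding the shared kernel parameters
#'   (`gamma`, `p`, `w`, `b`).
#' @param C,epsilon SVR penalty and tube width.
#' @param rf An [rf_config()] for the forest row.
#' @return Object of class `eval_report`: `comparison` data frame
#'   (`model`, `r2_cv`, `r2_train`, `rmse_train`, `r2_test`, `rmse_test`)
#'   and `predictions` (long data frame: `id`, `set`, `model`,
#'   `experimental`, `calculated`).
#' @export
compare_models <- function(x, y, split,
                           models = c("linear", "svr-mix", "svr-rbf",
                                      "svr-poly", "svr-linear", "rf"),
                           kernel_params = list(), C = 100, epsilon = 0.01,
                           rf = rf_config()) {
  x <- as.matrix(x)
  if (is.null(rownames(x))) rownames(x) <- as.character(seq_len(nrow(x)))
  if (is.null(names(y))) names(y) <- rownames(x)
  tr <- as.character(split$train_ids); te <- as.character(split$test_ids)
  if (!all(c(tr, te) %in% rownames(x))) stop("split ids not found in x")
  xtr <- x[tr, , drop = FALSE]; ytr <- y[tr]
  xte <- x[te, , drop = FALSE]; yte <- y[te]

  rows <- list(); preds <- list()
  for (m in models) {
    factory <- model_factory(m, kernel_params = kernel_params, C = C,
                             epsilon = epsilon, rf = rf)
    f <- factory(xtr, ytr)
    p_tr <- f(xtr); p_te <- f(xte)
    cv <- loocv(factory, xtr, ytr)
    rows[[m]] <- data.frame(
      model = m, r2_cv = cv$r2_cv,
      r2_train = r_squared(ytr, p_tr), rmse_train = rmse(ytr, p_tr),
      r2_test = r_squared(yte, p_te), rmse_test = rmse(yte, p_te))
    preds[[m]] <- data.frame(
      id = c(tr, te), set = rep(c("train", "test"), c(length(tr), length(te))),
      model = m, experimental = c(ytr, yte), calculated = c(p_tr, p_te))
  }
  structure(list(comparison = do.call(rbind, c(rows, make.row.names = FALSE)),
                 predictions = do.call(rbind, c(preds,
                                                make.row.names = FALSE))),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  print(x$comparison, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Write an evaluation report to CSV
#'
#' `comparison.csv` mirrors the model-comparison table layout;
#' `predictions.csv` holds experimental vs calculated activities per
#' compound and model.
#'
#' @param report An `eval_report`.
#' @param dir Output directory.
#' @export
write_eval_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(report$comparison, file.path(dir, "comparison.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(report$predictions, file.path(dir, "predictions.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(dir)
}
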