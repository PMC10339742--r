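#' Random-forest configuration
#'
#' The four hyperparameters tuned for the forest: `NT` — number of trees;
#' `MD` — maximum tree depth; `MS` — minimum samples required to split an
#' internal node; `ML` — minimum samples per leaf (pre-pruning). All splits
#' consider every descriptor (no feature subsampling) and trees are grown on
#' bootstrap samples of size n drawn with replacement.
#'
#' @param NT Number of trees, >= 1.
#' @param MD Maximum depth, >= 1.
#' @param MS Minimum samples to split, >= 2.
#' @param ML Minimum samples per leaf, >= 1 and <= MS.
#' @param seed Integer seed.
#' @return A list of class `rf_config`.
#' @export
rf_config <- function(NT = 500, MD = 10, MS = 2, ML = 1, seed = 1) {
  vals <- c(NT = NT, MD = MD, MS = MS, ML = ML)
  if (any(vals < 1) || any(vals != round(vals))) {
    stop("NT, MD, MS, ML must be positive integers")
  }
  if (NT < 1) stop("NT must be >= 1")
  if (ML > MS) stop("ML must be <= MS")
  structure(list(NT = as.integer(NT), MD = as.integer(MD),
                 MS = as.integer(MS), ML = as.integer(ML),
                 seed = as.integer(seed)), class = "rf_config")
}

#' Fit a random-forest regression
#'
#' Bagged regression trees honouring the four pre-pruning constraints of
#' [rf_config()]; the prediction is the mean of the per-tree predictions,
#' so it is bounded by the range of the training activities. Deterministic
#' for a fixed seed.
#'
#' @param x Descriptor matrix.
#' @param y Activity vector.
#' @param config An [rf_config()].
#' @return Object of class `rf_fit`.
#' @export
fit_rf <- function(x, y, config = rf_config()) {
  stopifnot(inherits(config, "rf_config"))
  x <- as.data.frame(as.matrix(x))
  fit <- ranger::ranger(
    y = y, x = x,
    num.trees = config$NT,
    max.depth = config$MD,
    min.node.size = config$MS,
    min.bucket = config$ML,
    mtry = ncol(x),
    replace = TRUE,
    sample.fraction = 1,
    seed = config$seed,
    num.threads = 1
  )
  structure(list(forest = fit, config = config, features = colnames(x)),
            class = "rf_fit")
}

#' Predict from a random-forest fit
#' @param model An `rf_fit`.
#' @param x Descriptor matrix for new compounds.
#' @return Numeric predictions.
#' @export
predict_rf <- function(model, x) {
  stopifnot(inherits(model, "rf_fit"))
  nd <- as.data.frame(as.matrix(x))[, model$features, drop = FALSE]
  stats::predict(model$forest, data = nd, num.threads = 1)$predictions
}

#' @export
predict.rf_fit <- function(object, newdata, ...) predict_rf(object, newdata)
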