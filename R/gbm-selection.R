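#' Gradient-boosted-tree descriptor importance
#'
#' Trains a gradient-boosted regression-tree ensemble (squared-error loss)
#' and scores every descriptor by one of the two standard importance
#' measures: `"split_gain"` — the total loss reduction accumulated at the
#' splits that use the descriptor — or `"coverage"` — the number of training
#' samples routed through those splits (for squared-error boosting the
#' library's cover statistic is exactly the per-node sample count). Both are
#' normalized to sum to one over all descriptors; descriptors never used by
#' any tree score zero. Coverage tends to favour high-cardinality
#' descriptors that appear in many deep splits, which is why split gain is
#' the default.
#'
#' @param x Numeric descriptor matrix.
#' @param y Activity vector (must not be constant).
#' @param method `"split_gain"` (default) or `"coverage"`.
#' @param gbm_params List of boosting hyperparameters: `nrounds` (trees,
#'   default 200), `max_depth` (4), `eta` (learning rate, 0.1).
#' @param seed Integer seed for the (deterministic, single-threaded) fit.
#' @return An object of class `importance_report`: data frame `ranking`
#'   (`descriptor`, `importance`, `cumulative`, ranked decreasing) plus the
#'   `method` and the per-descriptor named `importance` vector in column
#'   order.
#' @export
gbm_importance <- function(x, y, method = c("split_gain", "coverage"),
                           gbm_params = list(), seed = 1) {
  method <- match.arg(method)
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("X", seq_len(ncol(x)))
  if (stats::var(y) == 0) stop("constant response: importance undefined")
  params <- utils::modifyList(list(nrounds = 200, max_depth = 4, eta = 0.1),
                              gbm_params)
  booster <- with_seed(seed, {
    dtrain <- xgboost::xgb.DMatrix(x, label = y, nthread = 1)
    xgboost::xgb.train(
      params = list(max_depth = params$max_depth, eta = params$eta,
                    objective = "reg:squarederror", nthread = 1,
                    seed = seed),
      data = dtrain, nrounds = params$nrounds, verbose = 0)
  })
  imp <- xgboost::xgb.importance(model = booster)
  raw <- stats::setNames(rep(0, ncol(x)), colnames(x))
  col <- if (method == "split_gain") "Gain" else "Cover"
  raw[imp$Feature] <- imp[[col]]
  if (sum(raw) <= 0) stop("no splits were made; cannot rank descriptors")
  imp_norm <- raw / sum(raw)
  ord <- order(-imp_norm)
  ranking <- data.frame(descriptor = names(imp_norm)[ord],
                        importance = unname(imp_norm[ord]))
  ranking$cumulative <- cumsum(ranking$importance)
  structure(list(ranking = ranking, importance = imp_norm, method = method),
            class = "importance_report")
}

#' Select descriptors by cumulative importance
#'
#' Returns the smallest prefix of the importance ranking whose cumulative
#' normalized importance reaches `threshold`. With `threshold = 1` every
#' descriptor with nonzero importance is returned.
#'
#' @param report An `importance_report` from [gbm_importance()].
#' @param threshold Cumulative-importance cutoff in `(0, 1]`; default 0.85.
#' @return Character vector of selected descriptor names, most important
#'   first.
#' @export
select_cumulative <- function(report, threshold = 0.85) {
  stopifnot(inherits(report, "importance_report"))
  if (!(threshold > 0 && threshold <= 1)) {
    stop("threshold must lie in (0, 1]")
  }
  r <- report$ranking
  if (threshold == 1) return(r$descriptor[r$importance > 0])
  n_sel <- which(r$cumulative >= threshold - 1e-12)[1]
  if (is.na(n_sel)) n_sel <- nrow(r)
  r$descriptor[seq_len(n_sel)]
}

#' Pairwise Pearson correlation of a descriptor subset
#'
#' Computes the correlation matrix of the chosen descriptors and flags pairs
#' whose `|r|` reaches `flag_threshold` — a post-selection sanity check that
#' the selected set is not internally redundant. Zero-variance columns yield
#' NA entries which are reported via the `"undefined"` attribute rather than
#' silently propagated.
#'
#' @param x Numeric descriptor matrix.
#' @param subset Character vector of descriptor names (default: all).
#' @param flag_threshold Absolute correlation that triggers a flag; 0.5.
#' @return Correlation matrix with attributes `flagged` (data frame of
#'   offending pairs, possibly empty) and `undefined` (names of
#'   zero-variance columns). A warning is emitted when pairs are flagged.
#' @export
correlation_matrix <- function(x, subset = colnames(x), flag_threshold = 0.5) {
  x <- as.matrix(x)[, subset, drop = FALSE]
  if (nrow(x) < 2) stop("need at least two rows")
  vars <- apply(x, 2, stats::var)
  cm <- suppressWarnings(stats::cor(x))
  undefined <- colnames(x)[vars == 0]
  pairs <- which(abs(cm) >= flag_threshold & upper.tri(cm), arr.ind = TRUE)
  flagged <- data.frame(a = colnames(x)[pairs[, 1]],
                        b = colnames(x)[pairs[, 2]],
                        r = cm[pairs])
  if (nrow(flagged) > 0) {
    warning("descriptor pair(s) with |r| >= ", flag_threshold, ": ",
            paste(flagged$a, flagged$b, sep = "~", collapse = ", "))
  }
  attr(cm, "flagged") <- flagged
  attr(cm, "undefined") <- undefined
  cm
}

#' Write an importance report to CSV
#' @param report An `importance_report`.
#' @param path Output CSV path.
#' @export
write_importance <- function(report, path) {
  utils::write.csv(report$ranking, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
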