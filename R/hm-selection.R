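#' Pre-filter a descriptor matrix
#'
#' Applies the three standard descriptor pre-selection rules used before
#' stepwise multilinear modelling: (1) drop "non-generic" descriptors —
#' columns missing for at least one compound; (2) drop zero-variance
#' descriptors; (3) for every remaining pair with `|Pearson r|` above
#' `corr_threshold`, drop the member whose absolute correlation with the
#' activity is lower (ties keep the earlier column). Pairs are processed in
#' decreasing `|r|`, so the result carries no surviving pair above the
#' threshold and the operation is idempotent.
#'
#' @param x Numeric descriptor matrix (may contain NA).
#' @param y Activity vector (used to decide which member of a collinear pair
#'   survives).
#' @param corr_threshold Collinearity bar in `(0, 1]`; default 0.8.
#' @return Character vector of surviving descriptor names, in column order.
#' @export
prefilter <- function(x, y, corr_threshold = 0.8) {
  if (!(corr_threshold > 0 && corr_threshold <= 1)) {
    stop("corr_threshold must lie in (0, 1]")
  }
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("X", seq_len(ncol(x)))
  keep <- !apply(x, 2, anyNA)
  x2 <- x[, keep, drop = FALSE]
  vars <- apply(x2, 2, stats::var)
  x2 <- x2[, vars > 0, drop = FALSE]
  if (ncol(x2) < 2) return(colnames(x2))

  r_xy <- abs(as.numeric(stats::cor(x2, y)))
  r_xx <- abs(stats::cor(x2))
  diag(r_xx) <- 0
  alive <- rep(TRUE, ncol(x2))
  offending <- which(r_xx > corr_threshold & upper.tri(r_xx), arr.ind = TRUE)
  if (nrow(offending) > 0) {
    offending <- offending[order(-r_xx[offending]), , drop = FALSE]
    for (k in seq_len(nrow(offending))) {
      i <- offending[k, 1]; j <- offending[k, 2]
      if (alive[i] && alive[j]) {
        # drop the member less correlated with the activity; tie keeps i (< j)
        drop_j <- r_xy[j] < r_xy[i] || (r_xy[j] == r_xy[i])
        if (drop_j) alive[j] <- FALSE else alive[i] <- FALSE
      }
    }
  }
  colnames(x2)[alive]
}

#' Ordinary least squares with QSAR fit statistics
#'
#' Fits `y ~ X` by least squares and reports the coefficient of
#' determination, the Fisher criterion
#' `F = (R^2/k) / ((1 - R^2)/(n - k - 1))`, and the leave-one-out
#' cross-validated `R^2` (computed exactly through the hat matrix, the PRESS
#' identity for linear smoothers).
#'
#' @param x Numeric matrix of predictors (no intercept column).
#' @param y Numeric response.
#' @return An object of class `linear_model`: `intercept`, named
#'   `coefficients`, `r2`, `r2_cv`, `fisher_F`, `n_descriptors`, `n`,
#'   `fitted`, `descriptors`.
#' @export
fit_ols <- function(x, y) {
  x <- as.matrix(x)
  n <- nrow(x); k <- ncol(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("X", seq_len(k))
  if (n <= k + 1) stop("need more rows (", n, ") than descriptors + 1 (",
                       k + 1, ")")
  xm <- cbind(`(Intercept)` = 1, x)
  qr_ <- qr(xm)
  if (qr_$rank < ncol(xm)) {
    bad <- colnames(xm)[qr_$pivot[(qr_$rank + 1):ncol(xm)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  coefs <- qr.coef(qr_, y)
  fitted <- as.numeric(xm %*% coefs)
  res <- y - fitted
  sst <- sum((y - mean(y))^2)
  if (sst == 0) stop("response is constant")
  r2 <- 1 - sum(res^2) / sst
  h <- rowSums(qr.Q(qr_)[, seq_len(qr_$rank), drop = FALSE]^2)
  press <- sum((res / (1 - h))^2)
  r2_cv <- 1 - press / sst
  fisher_F <- (r2 / k) / ((1 - r2) / (n - k - 1))
  structure(list(
    intercept = unname(coefs[1]),
    coefficients = coefs[-1],
    r2 = r2, r2_cv = r2_cv, fisher_F = fisher_F,
    n_descriptors = k, n = n, fitted = fitted,
    descriptors = colnames(x)
  ), class = "linear_model")
}

#' Predict from a fitted linear model
#' @param object A `linear_model`.
#' @param newdata Matrix containing at least the model's descriptor columns.
#' @param ... Unused.
#' @export
predict.linear_model <- function(object, newdata, ...) {
  nd <- as.matrix(newdata)[, object$descriptors, drop = FALSE]
  as.numeric(nd %*% object$coefficients + object$intercept)
}

#' Render a linear model as an activity equation
#' @param model A `linear_model`.
#' @param response Left-hand-side label, default `"-lg(IC50)"`.
#' @param digits Digits per coefficient.
#' @return A single string, e.g. `-lg(IC50) = 2.31*FFP - 0.58*CHZ + 57.74`.
#' @export
format_equation <- function(model, response = "-lg(IC50)", digits = 2) {
  co <- model$coefficients
  terms <- sprintf("%s%s*%s",
                   ifelse(seq_along(co) == 1 & co >= 0, "",
                          ifelse(co >= 0, " + ", " - ")),
                   format(abs(round(co, digits)), trim = TRUE),
                   names(co))
  icpt <- model$intercept
  tail <- sprintf("%s%s", if (icpt >= 0) " + " else " - ",
                  format(abs(round(icpt, digits)), trim = TRUE))
  paste0(response, " = ", paste(terms, collapse = ""), tail)
}

#' @export
print.linear_model <- function(x, ...) {
  cat(format_equation(x), "\n")
  cat(sprintf("n = %d, k = %d, R2 = %.4f, R2cv = %.4f, F = %.2f\n",
              x$n, x$n_descriptors, x$r2, x$r2_cv, x$fisher_F))
  invisible(x)
}

# Best 2-descriptor pair by R^2 (equivalently F at fixed k), computed in
# closed form from the correlation structure:
# R^2(i,j) = (ri^2 + rj^2 - 2 ri rj rij) / (1 - rij^2).
best_pair <- function(x, y) {
  r <- as.numeric(stats::cor(x, y))
  rr <- stats::cor(x)
  num <- outer(r^2, r^2, "+") - 2 * outer(r, r) * rr
  den <- 1 - rr^2
  r2 <- num / den
  r2[!is.finite(r2)] <- -Inf
  diag(r2) <- -Inf
  idx <- which(r2 == max(r2), arr.ind = TRUE)[1, ]
  sort(as.integer(idx))
}

#' Greedy stepwise descriptor selection by the Fisher criterion
#'
#' Builds multilinear models of increasing size on a pre-filtered descriptor
#' matrix: the best 2-descriptor pair by the Fisher criterion first, then at
#' each size the descriptor that maximizes F among candidates not collinear
#' (`|r| <= corr_threshold`) with any already-selected descriptor. For every
#' size the model's `R^2`, LOOCV `R^2`, and F are recorded.
#'
#' @param x Numeric descriptor matrix (pre-filtered; see [prefilter()]).
#' @param y Activity vector.
#' @param max_k Largest model size to grow to (clamped, with a warning, to
#'   the number of available descriptors).
#' @param corr_threshold Collinearity bar reused inside the search.
#' @return An object of class `selection_curve`: `summary` data frame
#'   (`k`, `descriptor_added`, `r2`, `r2_cv`, `fisher_F`) and `models`, the
#'   fitted `linear_model` per size.
#' @export
stepwise_select <- function(x, y, max_k = 7, corr_threshold = 0.8) {
  x <- as.matrix(x)
  p <- ncol(x)
  if (p < 2) stop("need at least two descriptors after pre-filtering")
  if (max_k > p) {
    warning("max_k (", max_k, ") exceeds available descriptors (", p,
            "); clamping")
    max_k <- p
  }
  n <- nrow(x)
  if (max_k > n - 2) {
    warning("max_k clamped to n - 2 to keep models overdetermined")
    max_k <- n - 2
  }

  sel <- best_pair(x, y)
  rr <- abs(stats::cor(x))
  models <- list()
  rows <- list()
  fit <- fit_ols(x[, sel, drop = FALSE], y)
  models[[1]] <- fit
  rows[[1]] <- data.frame(k = 2,
                          descriptor_added = paste(colnames(x)[sel],
                                                   collapse = "+"),
                          r2 = fit$r2, r2_cv = fit$r2_cv,
                          fisher_F = fit$fisher_F)
  while (length(sel) < max_k) {
    remaining <- setdiff(seq_len(p), sel)
    ok <- remaining[apply(rr[remaining, sel, drop = FALSE] <= corr_threshold,
                          1, all)]
    if (length(ok) == 0) {
      warning("no non-collinear candidates left at k = ", length(sel) + 1)
      break
    }
    best <- NULL; best_F <- -Inf
    for (c_ in ok) {
      f <- tryCatch(fit_ols(x[, c(sel, c_), drop = FALSE], y),
                    error = function(e) NULL)
      if (!is.null(f) && f$fisher_F > best_F) {
        best_F <- f$fisher_F; best <- c_; best_fit <- f
      }
    }
    if (is.null(best)) break
    sel <- c(sel, best)
    models[[length(models) + 1]] <- best_fit
    rows[[length(rows) + 1]] <- data.frame(
      k = length(sel), descriptor_added = colnames(x)[best],
      r2 = best_fit$r2, r2_cv = best_fit$r2_cv, fisher_F = best_fit$fisher_F)
  }
  structure(list(summary = do.call(rbind, rows), models = models),
            class = "selection_curve")
}

#' Choose the model size where cross-validated fit plateaus
#'
#' Walks the selection curve and returns the model at the smallest size `k`
#' for which growing to `k + 1` improves LOOCV `R^2` by less than
#' `plateau_delta`. A single-entry curve returns that entry; a strictly
#' rising curve returns the largest size with a warning.
#'
#' @param curve A `selection_curve` from [stepwise_select()].
#' @param plateau_delta Minimum LOOCV `R^2` gain that counts as progress.
#' @return The chosen `linear_model` (with attribute `"k"`).
#' @export
choose_model <- function(curve, plateau_delta = 0.01) {
  stopifnot(inherits(curve, "selection_curve"))
  s <- curve$summary
  m <- nrow(s)
  if (m == 0) stop("empty selection curve")
  pick <- m
  if (m > 1) {
    gains <- diff(s$r2_cv)
    flat <- which(gains < plateau_delta)
    if (length(flat) > 0) {
      pick <- flat[1]
    } else {
      warning("r2_cv still rising at max size; returning the largest model")
    }
  }
  model <- curve$models[[pick]]
  attr(model, "k") <- s$k[pick]
  model
}

#' Write a selection curve to CSV
#' @param curve A `selection_curve`.
#' @param path Output CSV path.
#' @export
write_selection_curve <- function(curve, path) {
  utils::write.csv(curve$summary, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
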