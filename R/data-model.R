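#' Negative decadic log activity transform
#'
#' Converts a half-maximal inhibitory concentration (IC50, in micromolar) to
#' the activity scale used throughout the package, `-log10(IC50)`. Larger
#' values mean more potent inhibitors.
#'
#' @param ic50 Numeric vector of positive IC50 values (uM).
#' @return Numeric vector of activities, `-log10(ic50)`.
#' @examples
#' neg_log10_activity(16.17)  # -1.2087
#' neg_log10_activity(1)      # 0
#' @export
neg_log10_activity <- function(ic50) {
  if (!is.numeric(ic50) || anyNA(ic50)) {
    stop("ic50 must be numeric with no missing values")
  }
  if (any(ic50 <= 0)) {
    stop("ic50 must be strictly positive (log10 undefined at ",
         paste(which(ic50 <= 0), collapse = ", "), ")")
  }
  -log10(ic50)
}

#' Read a compound activity table
#'
#' Reads a CSV with one row per compound: `id`, `r1_group`, `ar_label`,
#' `ic50_um`, and optionally `printed_activity` (an activity value transcribed
#' from a source table, kept verbatim) and `is_test` (logical test-set flag).
#' A computed `activity` column (`-log10(ic50_um)`) is always added; when the
#' source prints its own activity it is preserved separately in
#' `printed_activity` so transcription discrepancies remain visible.
#'
#' @param path Path to the CSV file (RFC-4180, header required, UTF-8).
#' @return A `data.frame` of class `compound_table` with columns `id`
#'   (character), `r1_group`, `ar_label`, `ic50_um`, `activity`, and, when
#'   present in the file, `printed_activity` and `is_test`.
#' @seealso [xo_compound_table()] for the packaged xanthine-oxidase dataset.
#' @export
read_compound_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  required <- c("id", "r1_group", "ar_label", "ic50_um")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("compound table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  ic50 <- suppressWarnings(as.numeric(df$ic50_um))
  bad <- which(is.na(ic50) | ic50 <= 0)
  if (length(bad) > 0) {
    stop("non-positive or non-numeric ic50_um in row(s): ",
         paste(bad, collapse = ", "))
  }
  df$id <- as.character(df$id)
  df$ic50_um <- ic50
  df$activity <- neg_log10_activity(ic50)
  if ("is_test" %in% names(df)) df$is_test <- as.logical(df$is_test)
  class(df) <- c("compound_table", "data.frame")
  df
}

#' Packaged xanthine-oxidase inhibitor dataset
#'
#' The 30 amide-derivative XO inhibitors shipped with the package: compound
#' id, R1 substituent class, an opaque aryl-group label, measured IC50 (uM),
#' the activity value as printed in the source table, and the published
#' train/test split flag. Two printed activities (compounds 3 and 28) disagree
#' with `-log10(IC50)`; both values are retained.
#'
#' @return A `compound_table` data frame with 30 rows.
#' @export
xo_compound_table <- function() {
  read_compound_table(system.file("extdata", "xo_compounds.csv",
                                  package = "qsarmix", mustWork = TRUE))
}

#' Split compounds into training and test sets
#'
#' Draws a reproducible random partition of the compound ids into a training
#' and a test set. If the table carries `is_test` flags and any flag is TRUE,
#' the flags override the random draw (the published split is honoured).
#'
#' @param records A `compound_table` (or any data frame with an `id` column
#'   and optionally `is_test`).
#' @param n_train,n_test Sizes of the two sets; must sum to `nrow(records)`.
#' @param seed Integer seed for the random draw.
#' @return A list with character vectors `train_ids` and `test_ids`.
#' @export
random_split <- function(records, n_train, n_test, seed) {
  ids <- as.character(records$id)
  n <- length(ids)
  if (n_train + n_test != n) {
    stop("n_train + n_test (", n_train + n_test,
         ") must equal the number of records (", n, ")")
  }
  if (!is.null(records$is_test) && any(records$is_test, na.rm = TRUE)) {
    test <- ids[which(records$is_test)]
    train <- setdiff(ids, test)
    return(list(train_ids = train, test_ids = test))
  }
  test <- with_seed(seed, sort(sample.int(n, n_test)))
  list(train_ids = ids[-test], test_ids = ids[test])
}

#' Fit a per-column scaler
#'
#' Learns per-descriptor scaling parameters on a numeric matrix. The min-max
#' variant maps every column to `[0, 1]`; a constant column maps to 0 (its
#' minimum is stored so the inverse transform recovers it exactly). The
#' z-score variant centres and scales to unit standard deviation, with a
#' constant column mapping to 0 likewise.
#'
#' @param x Numeric matrix (rows = compounds, columns = descriptors).
#' @param variant `"minmax"` (default) or `"zscore"`.
#' @return An object of class `qsar_scaler`.
#' @seealso [scaler_apply()], [scaler_invert()]
#' @export
fit_scaler <- function(x, variant = c("minmax", "zscore")) {
  variant <- match.arg(variant)
  x <- as.matrix(x)
  if (nrow(x) < 1 || ncol(x) < 1) stop("cannot fit a scaler on an empty matrix")
  if (variant == "minmax") {
    lo <- apply(x, 2, min)
    hi <- apply(x, 2, max)
    span <- hi - lo
    span[span == 0] <- 1  # constant column convention: maps to 0
    sc <- list(variant = variant, center = lo, scale = span)
  } else {
    mu <- colMeans(x)
    sd_ <- apply(x, 2, stats::sd)
    sd_[sd_ == 0] <- 1
    sc <- list(variant = variant, center = mu, scale = sd_)
  }
  sc$names <- colnames(x)
  class(sc) <- "qsar_scaler"
  sc
}

#' Apply a fitted scaler
#' @param scaler A `qsar_scaler` from [fit_scaler()].
#' @param x Numeric matrix with the same columns the scaler was fitted on.
#' @return The scaled matrix.
#' @export
scaler_apply <- function(scaler, x) {
  stopifnot(inherits(scaler, "qsar_scaler"))
  x <- as.matrix(x)
  sweep(sweep(x, 2, scaler$center, "-"), 2, scaler$scale, "/")
}

#' Invert a fitted scaler
#' @inheritParams scaler_apply
#' @param x Matrix on the scaled scale.
#' @return The matrix on the original scale.
#' @export
scaler_invert <- function(scaler, x) {
  stopifnot(inherits(scaler, "qsar_scaler"))
  x <- as.matrix(x)
  sweep(sweep(x, 2, scaler$scale, "*"), 2, scaler$center, "+")
}

#' Serialize / restore a scaler as JSON
#' @param scaler A `qsar_scaler`.
#' @param path File path to write to.
#' @export
scaler_to_json <- function(scaler, path) {
  stopifnot(inherits(scaler, "qsar_scaler"))
  jsonlite::write_json(unclass(scaler), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname scaler_to_json
#' @export
scaler_from_json <- function(path) {
  sc <- jsonlite::read_json(path, simplifyVector = TRUE)
  sc$center <- as.numeric(sc$center)
  sc$scale <- as.numeric(sc$scale)
  class(sc) <- "qsar_scaler"
  sc
}

#' Read a descriptor matrix from CSV
#'
#' First column `id`, remaining columns numeric descriptors. Empty cells
#' become NA and form the missing mask (descriptors undefined for some
#' compounds, e.g. fluorine counts for F-free molecules computed by some
#' descriptor engines).
#'
#' @param path CSV path.
#' @return Numeric matrix with compound ids as rownames.
#' @export
read_descriptor_matrix <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1] != "id") stop("descriptor CSV must have 'id' as first column")
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df$id)
  m
}

#' Write a descriptor matrix to CSV
#' @param x Numeric matrix with rownames (compound ids).
#' @param path CSV path.
#' @export
write_descriptor_matrix <- function(x, path) {
  df <- data.frame(id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
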