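#' Specify a synthetic descriptor dataset
#'
#' Describes a compounds-by-descriptors matrix with the statistical features a
#' molecular-descriptor table presents to a QSAR pipeline: a handful of truly
#' informative descriptors, constant (zero-variance) descriptors, highly
#' collinear descriptor pairs, "non-generic" descriptors that are undefined
#' for some compounds, heterogeneous column scales, and an activity that is a
#' sparse linear combination of the informative descriptors plus an optional
#' smooth nonlinearity plus Gaussian noise.
#'
#' Informative descriptors are standard normal latents; each is published at a
#' scale `10^k`, `k` drawn from `{-2,...,2}`, to exercise normalization. Every
#' informative latent carries a coefficient of magnitude 1 and alternating
#' sign, so each contributes equal signal variance. `noise_sd` defaults to
#' `sd(signal)/snr` with `snr = 10`.
#'
#' @param n_compounds,n_descriptors Matrix dimensions (defaults 54 x 646).
#' @param n_informative Number of descriptors that truly drive the activity.
#' @param n_constant Number of zero-variance descriptors.
#' @param n_collinear_pairs Number of descriptor pairs built to have
#'   `|Pearson r| >= 0.8`.
#' @param nonlinearity `"none"`, `"quadratic"` (adds the square of the first
#'   informative latent) or `"interaction"` (adds the product of the first
#'   two).
#' @param snr Signal-to-noise ratio, `sd(signal)/noise_sd`; ignored when
#'   `noise_sd` is given explicitly.
#' @param noise_sd Gaussian noise standard deviation on the activity; `NULL`
#'   (default) derives it from `snr`.
#' @param missing_fraction Fraction of non-informative descriptor columns
#'   marked "non-generic": each gets NA for a few random compounds.
#' @param seed Integer seed.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_compounds = 54, n_descriptors = 646,
                           n_informative = 4, n_constant = 5,
                           n_collinear_pairs = 10,
                           nonlinearity = c("none", "quadratic", "interaction"),
                           snr = 10, noise_sd = NULL,
                           missing_fraction = 0.02, seed = 1) {
  nonlinearity <- match.arg(nonlinearity)
  if (n_informative + n_constant + 2 * n_collinear_pairs > n_descriptors) {
    stop("infeasible column budget: informative + constant + 2*collinear ",
         "pairs exceeds n_descriptors")
  }
  if (!is.null(noise_sd) && noise_sd < 0) stop("noise_sd must be >= 0")
  if (nonlinearity == "interaction" && n_informative < 2) {
    stop("interaction nonlinearity needs at least 2 informative descriptors")
  }
  structure(list(
    n_compounds = n_compounds, n_descriptors = n_descriptors,
    n_informative = n_informative, n_constant = n_constant,
    n_collinear_pairs = n_collinear_pairs, nonlinearity = nonlinearity,
    snr = snr, noise_sd = noise_sd, missing_fraction = missing_fraction,
    seed = as.integer(seed)
  ), class = "synthetic_spec")
}

#' Generate a synthetic descriptor matrix and activity
#'
#' Draws the dataset described by a [synthetic_spec()]. Collinear pairs are
#' built as `x2 = x1 + small noise` (target `|r| >= 0.8`, checked and
#' re-drawn if a draw falls short). The returned ground truth records which
#' descriptor columns are informative and their coefficients on the published
#' (scaled) descriptor values.
#'
#' @param spec A `synthetic_spec`.
#' @return A list with `descriptors` (numeric matrix, compound ids as
#'   rownames, NA entries for non-generic descriptors), `activity` (numeric
#'   vector), and `truth` (list: `informative` names, `coefficients` on the
#'   published scale, `latent_coefficients`, `nonlinearity`, `noise_sd`,
#'   `constant`, `collinear`, `missing` column names).
#' @export
generate_synthetic <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    n <- spec$n_compounds
    p <- spec$n_descriptors
    names_all <- sprintf("D%04d", seq_len(p))

    # assign roles to shuffled column positions
    roles <- rep("noise", p)
    pos <- sample.int(p)
    idx_inf <- pos[seq_len(spec$n_informative)]
    used <- spec$n_informative
    idx_const <- pos[used + seq_len(spec$n_constant)]
    used <- used + spec$n_constant
    idx_base <- idx_dup <- integer(0)
    if (spec$n_collinear_pairs > 0) {
      idx_base <- pos[used + seq_len(spec$n_collinear_pairs)]
      used <- used + spec$n_collinear_pairs
      idx_dup <- pos[used + seq_len(spec$n_collinear_pairs)]
    }

    # latent unit-variance values for every non-constant, non-duplicate column
    z <- matrix(stats::rnorm(n * p), n, p)
    scales <- 10^sample(-2:2, p, replace = TRUE)
    x <- sweep(z, 2, scales, "*")

    for (j in idx_const) x[, j] <- stats::runif(1, -5, 5)
    for (k in seq_along(idx_base)) {
      b <- idx_base[k]; d <- idx_dup[k]
      repeat {
        dup <- z[, b] + stats::rnorm(n, sd = 0.3)
        if (abs(stats::cor(dup, z[, b])) >= 0.8) break
      }
      x[, d] <- dup * scales[d]
    }

    # equal-magnitude alternating-sign coefficients on the unit latents
    beta_latent <- (-1)^(seq_len(spec$n_informative) - 1)
    signal <- as.numeric(z[, idx_inf, drop = FALSE] %*% beta_latent)
    g <- switch(spec$nonlinearity,
      none = 0,
      quadratic = z[, idx_inf[1]]^2,
      interaction = z[, idx_inf[1]] * z[, idx_inf[2]]
    )
    signal <- signal + g
    # theoretical signal sd: unit latents contribute 1 each; var(z^2) = 2,
    # var(z1*z2) = 1 for independent standard normals
    g_var <- switch(spec$nonlinearity, none = 0, quadratic = 2, interaction = 1)
    noise_sd <- if (is.null(spec$noise_sd)) {
      sqrt(spec$n_informative + g_var) / spec$snr
    } else {
      spec$noise_sd
    }
    activity <- signal + stats::rnorm(n, sd = noise_sd)

    # non-generic descriptors: NA for 1-3 random compounds each
    candidates <- setdiff(seq_len(p), c(idx_inf, idx_const))
    n_missing <- round(spec$missing_fraction * p)
    idx_miss <- if (n_missing > 0 && length(candidates) > 0) {
      sample(candidates, min(n_missing, length(candidates)))
    } else integer(0)
    for (j in idx_miss) {
      x[sample.int(n, sample(1:3, 1)), j] <- NA
    }

    colnames(x) <- names_all
    rownames(x) <- sprintf("C%02d", seq_len(n))
    roles[idx_inf] <- "informative"; roles[idx_const] <- "constant"
    roles[c(idx_base, idx_dup)] <- "collinear"

    truth <- list(
      informative = names_all[idx_inf],
      coefficients = stats::setNames(beta_latent / scales[idx_inf],
                                     names_all[idx_inf]),
      latent_coefficients = stats::setNames(beta_latent, names_all[idx_inf]),
      nonlinearity = spec$nonlinearity,
      noise_sd = noise_sd,
      constant = names_all[idx_const],
      collinear = Map(c, names_all[idx_base], names_all[idx_dup]),
      missing = names_all[idx_miss],
      roles = stats::setNames(roles, names_all)
    )
    list(descriptors = x, activity = stats::setNames(activity, rownames(x)),
         truth = truth)
  })
}

#' Write a synthetic dataset as plain-text fixture files
#'
#' Emits `descriptors.csv` (the dialect [read_descriptor_matrix()] reads),
#' `activity.csv` (`id,activity`), `truth.json`, and `spec.yaml` into `dir`.
#' Output is byte-stable for a fixed spec seed.
#'
#' @param data Result of [generate_synthetic()].
#' @param dir Output directory (created if absent).
#' @param spec Optional `synthetic_spec` to record alongside the data.
#' @return Invisibly, the vector of file paths written.
#' @export
write_fixture <- function(data, dir, spec = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  f_desc <- file.path(dir, "descriptors.csv")
  f_act <- file.path(dir, "activity.csv")
  f_truth <- file.path(dir, "truth.json")
  write_descriptor_matrix(data$descriptors, f_desc)
  utils::write.csv(
    data.frame(id = names(data$activity), activity = unname(data$activity)),
    f_act, row.names = FALSE, quote = FALSE)
  truth <- data$truth
  truth$roles <- NULL
  jsonlite::write_json(truth, f_truth, auto_unbox = TRUE, digits = NA)
  paths <- c(f_desc, f_act, f_truth)
  if (!is.null(spec)) {
    f_spec <- file.path(dir, "spec.yaml")
    yaml::write_yaml(unclass(spec), f_spec)
    paths <- c(paths, f_spec)
  }
  invisible(paths)
}

#' Read an activity fixture (`activity.csv` as written by `write_fixture`)
#' @param path Path to `activity.csv`.
#' @return Named numeric vector of activities.
#' @export
read_activity <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stats::setNames(df$activity, as.character(df$id))
}
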