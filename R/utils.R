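#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed`, then restores the
#' caller's RNG state, so every stochastic operation in the package is
#' reproducible without disturbing the user's random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Derive a per-stage seed from a master seed
#'
#' Stage seeds are `(master %% 1e6) * 1000 + stage`, kept below 2^31 so they
#' remain valid R integers. Documented so that pipeline runs are exactly
#' reproducible stage by stage.
#'
#' @param master Master integer seed.
#' @param stage Small non-negative stage index.
#' @return Integer seed.
#' @keywords internal
stage_seed <- function(master, stage) {
  as.integer((as.numeric(master) %% 1e6) * 1000 + stage)
}
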