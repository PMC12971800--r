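#' @importFrom stats rnorm runif rexp rlnorm quantile median sd qnorm pchisq
#'   approx setNames complete.cases
#' @importFrom utils head tail write.csv read.csv
NULL

# Condition constructors -------------------------------------------------

adipoct_error <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "adipoct_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

#' Error signalled when a segmentation stage cannot produce a usable result
#'
#' Segmentation failures map onto the cohort-level "tool failure" exclusion
#' reason: a batch run records them and moves on rather than aborting.
#' @name segmentation-failure
#' @keywords internal
NULL

seg_failure <- function(msg, stage = NA_character_) {
  adipoct_error(msg, "adipoct_segmentation_failure", stage = stage)
}

invalid_spec <- function(msg) adipoct_error(msg, "adipoct_invalid_spec")

# Reproducibility --------------------------------------------------------

# Evaluate `expr` under a given RNG seed without disturbing the caller's
# RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(old <- get0(".Random.seed", globalenv()))) {
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Derive a stream-specific 31-bit sub-seed from a master seed.
derive_seed <- function(seed, stream) {
  (as.double(seed) * 48271 + 7919 * stream) %% 2147483647
}

`%||%` <- function(a, b) if (is.null(a)) b else a
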