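#' @importFrom rlang abort warn inform .data :=
#' @importFrom tibble tibble as_tibble is_tibble
#' @importFrom stats pnorm pt pchisq qnorm qt rnorm runif sd setNames
#' @importFrom utils head modifyList
NULL

# Error helpers: keep the three failure classes distinct so callers (and the
# pipeline's failure isolation) can branch on them.
stop_config <- function(msg) abort(msg, class = "targetmr_config_error")
stop_data   <- function(msg) abort(msg, class = "targetmr_data_error")
stop_usage  <- function(msg) abort(msg, class = "targetmr_usage_error")

#' Derive independent sub-stream seeds from one master seed
#'
#' All randomness in the package flows from a single integer seed; each
#' consumer (simulation replicate, bootstrap, Monte-Carlo null) draws its own
#' sub-seed so streams never overlap across stages.
#'
#' @param seed master integer seed.
#' @param n number of sub-seeds to derive.
#' @return integer vector of length `n`, each in `[1, 2^31 - 2]`.
#' @keywords internal
derive_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

# Evaluate `expr` under `seed` without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

`%||%` <- function(x, y) if (is.null(x)) y else x

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
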