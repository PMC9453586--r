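#' @importFrom rlang %||% abort warn
#' @importFrom stats quantile rnorm runif rbinom sd setNames predict
#' @importFrom utils head tail
NULL

# Deterministic 31-bit seed derived from a parent seed and a stage name, so a
# single top-level seed drives every stage without seed reuse across stages.
#' Derive a stage seed from a global seed
#'
#' Hashes a stage label together with a parent seed into a new seed in
#' `[0, 2^31 - 1]`. Used throughout the package so that one experiment-level
#' seed deterministically controls simulation, shuffling, initialization and
#' training.
#'
#' @param seed Integer parent seed.
#' @param stage Character label of the consuming stage (e.g. `"simulate"`).
#' @return A single integer seed.
#' @export
#' @examples
#' derive_seed(1, "simulate")
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(stage))
  m <- 2147483647
  h <- seed %% m
  for (ch in utf8ToInt(stage)) {
    h <- (h * 131 + ch) %% m
  }
  as.integer(h)
}

# Run code with a locally set RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# Truncated normal by rejection; bounds are wide relative to sd in all uses.
rtruncnorm <- function(n, mean, sd, lower, upper) {
  out <- rnorm(n, mean, sd)
  bad <- which(out < lower | out > upper)
  while (length(bad) > 0) {
    out[bad] <- rnorm(length(bad), mean, sd)
    bad <- which(out < lower | out > upper)
  }
  out
}

`%+na%` <- function(x, y) ifelse(is.na(x), y, x)

stop_named <- function(msg, ...) abort(sprintf(msg, ...), class = "labforecast_error")
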