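#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor cov median pf phyper quantile rnorm runif sd mad ks.test
#' @importFrom utils head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Group label vocabulary
#'
#' The three experimental arms of the fly sepsis-survival design: untouched
#' controls, sterile-needle-pricked flies, and infected flies rescued with an
#' oral antibiotic.
#' @export
GROUP_LEVELS <- c("unmanipulated", "sham", "sepsis_survivor")

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
# Keeps seeded entry points free of silent global side effects.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    seed <- as.integer(seed)
    if (is.na(seed)) stop("seed must be coercible to integer", call. = FALSE)
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

# Derive a child seed from a master seed; stays below 2^31.
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 1009 + offset) %% 2147483647L)
}

stop_fly <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warn_fly <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
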