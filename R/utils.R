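#' @keywords internal
"_PACKAGE"

## NULL coalescing used throughout
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible child seed from a master seed
#'
#' Mixes a master seed with one or more integer stream identifiers through a
#' Lehmer-style multiplicative congruential step, so that every random draw in
#' the package is traceable to a single master seed without consecutive seeds
#' colliding. Result is always a valid 32-bit R seed.
#'
#' @param seed Integer master seed.
#' @param ... Integer stream identifiers (e.g. repeat number, fold number).
#' @return A single integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, ...) {
  ks <- c(...)
  m <- 2147483647 # 2^31 - 1, prime
  s <- as.double(seed) %% m
  for (k in ks) {
    s <- (s * 48271 + abs(as.double(k)) + 1) %% m
  }
  as.integer(s)
}

## Run `expr` under set.seed(seed), restoring the caller's RNG state afterwards
## so that seeded package functions do not perturb the global random stream.
local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
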