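#' @keywords internal
#' @useDynLib bymsir, .registration = TRUE
#' @importFrom Rcpp sourceCpp
"_PACKAGE"

## Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
## All stochastic operations in the package funnel through this so that a
## single user-supplied seed makes every artefact reproducible.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

## Deterministic sub-stream seed for a named operation, kept within 32-bit
## integer range.
derive_seed <- function(seed, offset) {
  (as.integer(seed) + as.integer(offset)) %% .Machine$integer.max
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if <- function(cond, ...) if (isTRUE(cond)) stop(..., call. = FALSE)
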