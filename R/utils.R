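#' @keywords internal
"_PACKAGE"

# Argument checking helpers -----------------------------------------------

stop_invalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

assert_scalar_num <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_invalid("`%s` must be a finite numeric scalar", name)
  }
  if (x < lower || x > upper) {
    stop_invalid("`%s` = %g out of range [%g, %g]", name, x, lower, upper)
  }
  invisible(x)
}

assert_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    stop_invalid("`%s` must be TRUE or FALSE", name)
  }
  invisible(x)
}

#' Derive a child seed from a base seed
#'
#' Deterministic mixing used to hand independent substreams to subjects,
#' replicates and pipeline stages while keeping every stream reproducible
#' from one top-level seed. Result stays within 32-bit integer range.
#'
#' @param seed integer base seed.
#' @param ... one or more integer offsets (stage index, subject index, ...).
#' @return An integer seed.
#' @export
derive_seed <- function(seed, ...) {
  offs <- c(...)
  s <- as.double(seed) %% 2147483647
  for (o in offs) {
    s <- (s * 48271 + as.double(o) * 10007 + 1) %% 2147483647
  }
  as.integer(s)
}

# Run code with a local RNG state so package functions do not disturb the
# caller's random stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
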