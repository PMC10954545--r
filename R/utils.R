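#' Evaluate an expression with a temporary RNG seed
#'
#' Sets the seed for the duration of `expr` and restores the caller's RNG
#' state afterwards, so seeded generators do not disturb the global stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
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
  })
  set.seed(as.integer(seed))
  expr
}

# derive a child seed below 2^31 from a parent seed and a stream label
derive_seed <- function(seed, what) {
  h <- sum(utf8ToInt(what) * seq_along(utf8ToInt(what)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

stopifnot_scalar_num <- function(x, name, min = -Inf, strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("`%s` must be a single number", name), call. = FALSE)
  }
  if (strict_min && x <= min) {
    stop(sprintf("`%s` must be > %g", name, min), call. = FALSE)
  }
  if (!strict_min && x < min) {
    stop(sprintf("`%s` must be >= %g", name, min), call. = FALSE)
  }
  invisible(x)
}
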