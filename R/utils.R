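#' Run an expression under a temporary RNG seed
#'
#' Sets the seed for the duration of the calling function and restores the
#' caller's RNG state on exit, so seeded simulations do not perturb the global
#' random stream. A `NULL` seed leaves the current stream untouched.
#'
#' @param seed integer seed or `NULL`.
#' @param envir environment whose exit handler restores the RNG state.
#' @return invisibly, `NULL`.
#' @keywords internal
local_seed <- function(seed, envir = parent.frame()) {
  if (is.null(seed)) return(invisible(NULL))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_seed <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", globalenv()) else NULL
  expr <- if (!is.null(old)) {
    bquote(assign(".Random.seed", .(old), globalenv()))
  } else {
    quote(if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()))
  }
  do.call(on.exit, list(expr, add = TRUE), envir = envir)
  set.seed(as.integer(seed))
  invisible(NULL)
}

# n-1-th harmonic number a_n = 1 + 1/2 + ... + 1/(n-1): the Watterson
# normaliser E[S] = a_n * theta
a_n <- function(n) {
  stopifnot(n >= 2)
  sum(1 / seq_len(n - 1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
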