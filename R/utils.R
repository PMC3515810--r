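# Internal helpers shared across modules.

#' Evaluate code under a temporary RNG seed
#'
#' Restores the caller's RNG state on exit so that simulation helpers are
#' deterministic for a given seed without disturbing the global stream.
#' @noRd
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
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
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

#' Derive a child seed from a master seed
#'
#' Deterministic integer mixing so each well/field gets its own stream.
#' Kept below 2^31 - 1 because R seeds are 32-bit integers.
#' @noRd
derive_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed) %% 2147483647
  for (i in idx) {
    s <- (s * 48271 + as.double(i) * 104729 + 12345) %% 2147483647
  }
  as.integer(s)
}

#' Gauss-Legendre nodes and weights on [-1, 1]
#'
#' Golub-Welsch eigenvalue construction; results are cached per n.
#' @noRd
gauss_legendre <- function(n) {
  key <- as.character(n)
  cached <- .gl_cache[[key]]
  if (!is.null(cached)) return(cached)
  i <- seq_len(n - 1)
  b <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- b
  J[cbind(i + 1, i)] <- b
  e <- eigen(J, symmetric = TRUE)
  out <- list(nodes = e$values, weights = 2 * e$vectors[1, ]^2)
  .gl_cache[[key]] <- out
  out
}

.gl_cache <- new.env(parent = emptyenv())

#' Rescale Gauss-Legendre rule to [a, b]
#' @noRd
gauss_legendre_ab <- function(n, a, b) {
  gl <- gauss_legendre(n)
  list(nodes = (b - a) / 2 * gl$nodes + (a + b) / 2,
       weights = (b - a) / 2 * gl$weights)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ts <- function(...) stop(..., call. = FALSE)
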