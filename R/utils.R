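# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the caller's RNG state so seeded primitives do not
#' perturb the session stream. Generator kinds are pinned for portability.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  expr
}

# derive a stream-specific child seed, kept below 2^31
child_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1000003 + offset) %% 2147483647L)
}

clip01 <- function(x, lo = 0, hi = 255) pmin(pmax(x, lo), hi)

#' Quantize intensities to 8-bit integers
#'
#' Rounds half away from zero, then clips to `[0, 255]`. Used at every point
#' where an image leaves the package (file writes); all internal arithmetic
#' stays in double precision.
#'
#' @param x numeric matrix of intensities.
#' @return integer-valued numeric matrix in `[0, 255]`.
#' @export
quantize8 <- function(x) {
  q <- sign(x) * floor(abs(x) + 0.5)  # round half away from zero
  clip01(q)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

check_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) stopf("`%s` must be TRUE or FALSE", name)
  x
}
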