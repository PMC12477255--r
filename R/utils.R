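# Internal helpers: seeded RNG scoping and deterministic sub-seed derivation.

#' Evaluate an expression under a local RNG seed
#'
#' Saves and restores `.Random.seed` so seeded generator calls do not
#' perturb the caller's RNG stream.
#' @noRd
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Derive a deterministic 31-bit sub-seed from a base seed and string tags
#'
#' Simple multiplicative string hash; collisions are harmless (streams stay
#' reproducible) but distinct tags almost surely get distinct streams.
#' @noRd
derive_seed <- function(seed, ...) {
  tags <- paste(c(as.character(seed), vapply(list(...), as.character, "")),
                collapse = "|")
  h <- 0
  for (ch in utf8ToInt(tags)) h <- (h * 31 + ch) %% 2147483581L
  as.integer(h + 1L)
}

#' arcsinh transform with cofactor (CyTOF convention)
#'
#' @param x raw intensities.
#' @param cofactor positive cofactor; mass cytometry convention is 5.
#' @return `asinh(x / cofactor)`.
#' @export
arcsinh_transform <- function(x, cofactor = 5) {
  stopifnot(cofactor > 0)
  asinh(x / cofactor)
}

# Inverse of arcsinh_transform, truncated at zero (ion counts are nonnegative)
#' @noRd
arcsinh_inverse <- function(z, cofactor = 5) {
  pmax(cofactor * sinh(z), 0)  # argument order preserves matrix dims
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# stop()/warning() wrappers with a consistent condition class
#' @noRd
cp_stop <- function(...) stop(sprintf(...), call. = FALSE)
#' @noRd
cp_warn <- function(...) warning(sprintf(...), call. = FALSE)
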