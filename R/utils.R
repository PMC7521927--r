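# Internal numerical helpers shared across modules.

#' Trapezoidal integral on an arbitrary grid
#' @param x grid (strictly increasing)
#' @param y values at `x`
#' @return scalar integral
#' @keywords internal
#' @noRd
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}

#' Derive a reproducible sub-seed from a master seed and a stream name
#'
#' All randomness in the package flows from one master seed through named
#' substreams so modules can be generated (and tested) independently while the
#' whole pipeline stays bit-reproducible. Kept below 2^31 - 1.
#' @param seed master seed (integer)
#' @param name substream name
#' @return integer seed
#' @export
derive_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  h <- 0
  for (cc in utf8ToInt(name)) h <- (h * 131 + cc) %% 2147483647
  as.integer(((seed %% 1048573) * 1299709 + h * 31 + 17) %% 2147483629 + 1)
}

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
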