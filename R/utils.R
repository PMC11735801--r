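# Internal helpers shared across modules.

#' Clip to the 8-bit range and quantise (round half up)
#'
#' Matches the 8-bit conversion applied to raw OCT scans: values are clipped
#' to \[0, 255\] and rounded with ties going up (`floor(x + 0.5)`).
#'
#' @param x numeric vector or array.
#' @return integer-valued numeric object of the same shape, in \[0, 255\].
#' @keywords internal
clip_quantise <- function(x) {
  pmin(pmax(floor(x + 0.5), 0), 255)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG state is restored afterwards. `seed = NULL` leaves the RNG alone.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Derive child seeds from a master seed
#'
#' All randomness in the package flows from one integer seed. Child seeds for
#' sub-tasks (one volume of a time series, one replicate, ...) are derived by
#' the fixed affine rule `(seed * 48271 + 9973 * i) mod (2^31 - 1)`, keeping
#' every seed a valid 32-bit integer.
#'
#' @param seed master integer seed.
#' @param n number of child seeds.
#' @return integer vector of length `n`.
#' @export
split_seed <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1, n >= 1)
  m <- 2147483647
  as.integer((as.numeric(seed) %% m * 48271 + 9973 * seq_len(n)) %% m)
}

# Most frequent intensity level of a volume; ties broken toward the lowest
# level. Used as the fill value for rotation and flattening.
background_mode <- function(x) {
  tab <- tabulate(as.integer(x) + 1L, nbins = 256L)
  which.max(tab) - 1L
}

# Stop unless all dims positive.
check_shape <- function(shape) {
  if (length(shape) != 3 || any(!is.finite(shape)) || any(shape < 1))
    stop("shape must be three positive integers (nx, ny, nz)", call. = FALSE)
  as.integer(shape)
}
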