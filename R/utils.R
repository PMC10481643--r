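# Internal numerical helpers shared across modules.

#' Numerically stable log(sum(exp(x)))
#' @param x numeric vector
#' @return scalar
#' @keywords internal
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Evaluate `expr` under `set.seed(seed)` while preserving the caller's RNG
# state. seed = NULL leaves the global stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  eval.parent(substitute(expr))
}

#' Replace missing values with the nearest present value in time
#'
#' Ties between an equally distant earlier and later neighbour resolve to
#' the earlier one.
#'
#' @param x numeric vector with possible `NA`s
#' @return vector of the same length without `NA`s
#' @keywords internal
impute_nearest <- function(x) {
  if (!anyNA(x)) return(x)
  idx <- which(!is.na(x))
  if (length(idx) == 0L) stop("cannot impute a series that is entirely missing")
  pos <- seq_along(x)
  li <- pmax(findInterval(pos, idx), 1L)            # nearest present at/before
  ri <- pmin(findInterval(pos, idx) + 1L, length(idx))
  left <- idx[li]
  right <- idx[ri]
  use <- ifelse(abs(pos - left) <= abs(pos - right), left, right)
  x[use]
}

# Wrap an angle (degrees) into (-180, 180].
wrap_angle <- function(a) {
  a - 360 * ceiling((a - 180) / 360)
}

# Gaussian smoothing with reflected boundaries (kernel truncated at 4 sigma).
gaussian_smooth <- function(x, sigma, radius = ceiling(4 * sigma)) {
  n <- length(x)
  if (sigma <= 0 || n < 2L) return(x)
  r <- min(radius, n - 1L)
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  xp <- c(x[r:1], x, x[n:(n - r + 1L)])
  y <- stats::filter(xp, k, sides = 2)
  as.numeric(y[(r + 1L):(r + n)])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
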