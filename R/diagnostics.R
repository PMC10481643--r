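# Convergence diagnostics for the Metropolis-within-Gibbs posterior.

#' Split-chain potential scale reduction (R-hat)
#'
#' Each chain is split in half and the standard between/within variance
#' ratio is computed over the split chains. Values near 1 indicate that the
#' chains agree; constant parameters return `NA`.
#'
#' @param x iterations x chains matrix of draws for one parameter
#' @return scalar R-hat
#' @export
split_rhat <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 4L) return(NA_real_)
  half <- floor(n / 2L)
  sp <- cbind(x[seq_len(half), , drop = FALSE],
              x[(n - half + 1L):n, , drop = FALSE])
  m <- ncol(sp); nn <- nrow(sp)
  mu <- colMeans(sp)
  s2 <- apply(sp, 2L, stats::var)
  W <- mean(s2)
  B <- nn * stats::var(mu)
  if (!is.finite(W) || W <= 0) return(NA_real_)
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}

#' Effective sample size across chains
#'
#' Uses the chain-averaged autocorrelation function with Geyer's initial
#' positive-sequence truncation: lags are accumulated in pairs until a pair
#' sum turns negative.
#'
#' @param x iterations x chains matrix of draws for one parameter
#' @param max_lag largest autocorrelation lag considered
#' @return scalar effective sample size
#' @export
ess_mean <- function(x, max_lag = 200L) {
  x <- as.matrix(x)
  n <- nrow(x); m <- ncol(x)
  if (n < 4L) return(NA_real_)
  L <- min(max_lag, n - 2L)
  rho <- matrix(0, L + 1L, m)
  ok <- logical(m)
  for (j in seq_len(m)) {
    if (stats::var(x[, j]) <= 0) next
    a <- stats::acf(x[, j], lag.max = L, plot = FALSE)$acf[, 1L, 1L]
    rho[, j] <- a
    ok[j] <- TRUE
  }
  if (!any(ok)) return(NA_real_)
  r <- rowMeans(rho[, ok, drop = FALSE])
  tau <- 1
  lag <- 1L
  while (lag + 1L <= L) {
    pair <- r[lag + 1L] + r[lag + 2L]
    if (!is.finite(pair) || pair < 0) break
    tau <- tau + 2 * pair
    lag <- lag + 2L
  }
  max(m * n / tau, 1)
}

# Diagnostics table over every parameter of a draws x chains x params array.
mcmc_diagnostics <- function(samples) {
  pars <- dimnames(samples)[[3L]]
  rhat <- numeric(length(pars))
  ess <- numeric(length(pars))
  for (i in seq_along(pars)) {
    x <- samples[, , i, drop = FALSE]
    dim(x) <- dim(samples)[1:2]
    rhat[i] <- split_rhat(x)
    ess[i] <- ess_mean(x)
  }
  data.frame(parameter = pars, rhat = rhat, ess = ess,
             stringsAsFactors = FALSE)
}
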