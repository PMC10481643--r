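# Widely applicable information criterion over pointwise log-likelihoods.

#' WAIC from a pointwise log-likelihood matrix
#'
#' `lppd = sum_t log mean_d exp(ll[d, t])` (computed with log-sum-exp
#' stability), `p_waic = sum_t var_d(ll[d, t])`, and
#' `waic = -2 * (lppd - p_waic)`. Lower is better.
#'
#' @param x a draws x trials matrix of pointwise log-likelihoods, or an
#'   `rl_posterior` (whose matrix is used)
#' @return object of class `waic_fit`: list with `lppd`, `p_waic`, `waic`,
#'   `n_trials`, `n_draws`
#' @export
compute_waic <- function(x) {
  if (inherits(x, "rl_posterior")) x <- x$pointwise_loglik
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("WAIC needs at least 2 posterior draws")
  S <- nrow(x)
  lppd <- sum(apply(x, 2L, logsumexp) - log(S))
  p_waic <- sum(apply(x, 2L, stats::var))
  structure(list(lppd = lppd, p_waic = p_waic,
                 waic = -2 * (lppd - p_waic),
                 n_trials = ncol(x), n_draws = S),
            class = "waic_fit")
}

#' @export
print.waic_fit <- function(x, ...) {
  cat(sprintf("<waic_fit> waic %.2f (lppd %.2f, p_waic %.2f; %d trials, %d draws)\n",
              x$waic, x$lppd, x$p_waic, x$n_trials, x$n_draws))
  invisible(x)
}

#' Rank model variants by WAIC
#'
#' @param fits named list of `rl_posterior` objects (or pointwise matrices);
#'   names default to each fit's model-spec name
#' @return data frame, one row per model, ordered by WAIC (best first), with
#'   `lppd`, `p_waic`, `waic`, `delta_waic` and `rank`
#' @export
waic_compare <- function(fits) {
  if (is.null(names(fits)) || any(!nzchar(names(fits))))
    names(fits) <- vapply(fits, function(f)
      if (inherits(f, "rl_posterior")) f$spec$name else "model", "")
  rows <- lapply(names(fits), function(nm) {
    w <- compute_waic(fits[[nm]])
    data.frame(model = nm, lppd = w$lppd, p_waic = w$p_waic, waic = w$waic,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$waic), ]
  out$delta_waic <- out$waic - out$waic[1L]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
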