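# Hierarchical Bayesian inference over cohorts of sessions.

#' MCMC settings for the hierarchical fit
#'
#' @param chains independent chains (run sequentially with distinct seeds)
#' @param warmup adaptation iterations discarded per chain
#' @param draws retained iterations per chain
#' @param seed master seed; per-chain seeds are derived from it
#' @param rhat_warn split-chain convergence threshold above which a warning
#'   names the offending parameters
#' @param ess_warn minimum effective sample size before warning
#' @return list of class `mcmc_control`
#' @export
mcmc_control <- function(chains = 4L, warmup = 1000L, draws = 1000L,
                         seed = 1L, rhat_warn = 1.01, ess_warn = 400) {
  stopifnot(chains >= 1L, warmup >= 0L, draws >= 2L)
  structure(list(chains = as.integer(chains), warmup = as.integer(warmup),
                 draws = as.integer(draws), seed = as.integer(seed),
                 rhat_warn = rhat_warn, ess_warn = ess_warn),
            class = "mcmc_control")
}

#' Prior settings for the hierarchical model
#'
#' Learning rates live on the logit scale and inverse temperatures on the
#' log scale; group hypermeans get normal priors and hyperscales half-normal
#' priors. With rewards on the 0--100 value scale, plausible inverse
#' temperatures are of order 0.01--0.2, hence the `log(0.05)` prior centre.
#' Shared initial odor values get independent normal priors and are anchored
#' to mean zero for identifiability (softmax probabilities are invariant to
#' a constant shift of all values).
#'
#' @param mu_alpha_loc,mu_alpha_scale normal prior on logit-scale alpha
#'   hypermeans
#' @param sigma_alpha_scale half-normal prior scale on alpha hyperscales
#' @param mu_beta_loc,mu_beta_scale normal prior on log-scale beta hypermeans
#' @param sigma_beta_scale half-normal prior scale on beta hyperscales
#' @param v_scale normal prior standard deviation of the shared initial
#'   values (value units)
#' @return list of class `prior_control`
#' @export
prior_control <- function(mu_alpha_loc = 0, mu_alpha_scale = 1.5,
                          sigma_alpha_scale = 1,
                          mu_beta_loc = log(0.05), mu_beta_scale = 1.5,
                          sigma_beta_scale = 1, v_scale = 25) {
  structure(list(mu_alpha_loc = mu_alpha_loc, mu_alpha_scale = mu_alpha_scale,
                 sigma_alpha_scale = sigma_alpha_scale,
                 mu_beta_loc = mu_beta_loc, mu_beta_scale = mu_beta_scale,
                 sigma_beta_scale = sigma_beta_scale, v_scale = v_scale),
            class = "prior_control")
}

# Flatten a session list into the arrays the sampler consumes.
pack_sessions <- function(sessions, config) {
  if (length(sessions) == 0L) stop("no sessions to fit")
  choice <- integer(0); reward <- integer(0); phase <- integer(0)
  offsets <- 0L
  animals <- list(); tmap <- list()
  for (sess in sessions) {
    stopifnot(inherits(sess, "choice_session"))
    cd <- completed_trials(sess)
    if (nrow(cd) == 0L)
      stop("session for mouse ", sess$mouse_id, " has no completed trials")
    choice <- c(choice, cd$choice - 1L)
    reward <- c(reward, as.integer(cd$rewarded))
    phase <- c(phase, match(cd$phase, task_phases()) - 1L)
    offsets <- c(offsets, offsets[length(offsets)] + nrow(cd))
    animals[[length(animals) + 1L]] <- data.frame(
      mouse_id = sess$mouse_id, group = sess$group, stringsAsFactors = FALSE)
    tmap[[length(tmap) + 1L]] <- data.frame(
      mouse_id = sess$mouse_id, phase = cd$phase,
      choice_index = stats::ave(seq_len(nrow(cd)), cd$phase, FUN = seq_along),
      stringsAsFactors = FALSE)
  }
  animals <- do.call(rbind, animals)
  groups <- unique(animals$group)
  list(choice = choice, reward = reward, phase = phase, offsets = offsets,
       group_idx = match(animals$group, groups) - 1L, groups = groups,
       animals = animals, trial_map = do.call(rbind, tmap))
}

# Column names matching the sampler's storage layout.
raw_param_names <- function(groups, animals, Pa, Pb, n_odors) {
  mpa <- if (Pa == 2L) c("acq", "test") else "shared"
  mpb <- if (Pb == 2L) c("acq", "test") else "shared"
  gv <- function(stub, mp) as.vector(t(outer(groups, mp, function(g, p)
    sprintf("%s[%s,%s]", stub, g, p))))
  kv <- function(stub, mp) as.vector(t(outer(animals, mp, function(k, p)
    sprintf("%s[%s,%s]", stub, k, p))))
  c(gv("mu_alpha", mpa), gv("log_sigma_alpha", mpa),
    gv("mu_beta", mpb), gv("log_sigma_beta", mpb),
    kv("z_alpha", mpa), kv("z_beta", mpb),
    sprintf("u[%d]", seq_len(n_odors - 1L)), "lp__")
}

# Derived natural-scale quantities per draw for one chain's raw matrix.
derive_chain <- function(raw, pk, Pa, Pb, n_odors) {
  groups <- pk$groups
  ids <- pk$animals$mouse_id
  G <- length(groups); K <- length(ids)
  col_of <- function(nm) raw[, nm, drop = TRUE]
  out <- list()
  ja <- function(ph) if (Pa == 2L) ph else "shared"
  jb <- function(ph) if (Pb == 2L) ph else "shared"
  for (g in groups) {
    for (ph in c("acq", "test")) {
      out[[sprintf("alpha_grp[%s,%s]", g, ph)]] <-
        stats::plogis(col_of(sprintf("mu_alpha[%s,%s]", g, ja(ph))))
      out[[sprintf("beta_grp[%s,%s]", g, ph)]] <-
        exp(col_of(sprintf("mu_beta[%s,%s]", g, jb(ph))))
    }
    out[[sprintf("delta_alpha_grp[%s]", g)]] <-
      out[[sprintf("alpha_grp[%s,test]", g)]] - out[[sprintf("alpha_grp[%s,acq]", g)]]
    out[[sprintf("delta_beta_grp[%s]", g)]] <-
      out[[sprintf("beta_grp[%s,test]", g)]] - out[[sprintf("beta_grp[%s,acq]", g)]]
    mpa <- if (Pa == 2L) c("acq", "test") else "shared"
    mpb <- if (Pb == 2L) c("acq", "test") else "shared"
    for (mp in mpa)
      out[[sprintf("sigma_alpha[%s,%s]", g, mp)]] <-
        exp(col_of(sprintf("log_sigma_alpha[%s,%s]", g, mp)))
    for (mp in mpb)
      out[[sprintf("sigma_beta[%s,%s]", g, mp)]] <-
        exp(col_of(sprintf("log_sigma_beta[%s,%s]", g, mp)))
  }
  # shared initial values: last odor pinned at 0 on the free scale, then
  # the whole vector centred to mean zero
  u <- raw[, sprintf("u[%d]", seq_len(n_odors - 1L)), drop = FALSE]
  m <- rowSums(u) / n_odors
  for (i in seq_len(n_odors - 1L)) out[[sprintf("v[%d]", i)]] <- u[, i] - m
  out[[sprintf("v[%d]", n_odors)]] <- -m
  for (k in seq_len(K)) {
    g <- pk$animals$group[k]
    for (ph in c("acq", "test")) {
      mu <- col_of(sprintf("mu_alpha[%s,%s]", g, ja(ph)))
      sg <- exp(col_of(sprintf("log_sigma_alpha[%s,%s]", g, ja(ph))))
      z <- col_of(sprintf("z_alpha[%s,%s]", ids[k], ja(ph)))
      out[[sprintf("alpha[%s,%s]", ids[k], ph)]] <- stats::plogis(mu + sg * z)
      mu <- col_of(sprintf("mu_beta[%s,%s]", g, jb(ph)))
      sg <- exp(col_of(sprintf("log_sigma_beta[%s,%s]", g, jb(ph))))
      z <- col_of(sprintf("z_beta[%s,%s]", ids[k], jb(ph)))
      out[[sprintf("beta[%s,%s]", ids[k], ph)]] <- exp(pmin(mu + sg * z, 25))
    }
  }
  do.call(cbind, out)
}

#' Fit the hierarchical softmax Q-learning model to a cohort
#'
#' Per-animal phase-specific learning rates and inverse temperatures are
#' drawn from group-level distributions (normal on the logit and log scales
#' respectively, non-centred parameterization); initial odor values are
#' shared by all animals and groups. Sampling is adaptive
#' Metropolis-within-Gibbs with per-animal block proposals, scalar
#' hyperparameter proposals and a joint proposal for the shared values;
#' proposal scales adapt during warmup only. Convergence is summarized by
#' split-chain R-hat and effective sample size per parameter; a warning
#' names parameters exceeding the configured thresholds.
#'
#' @param sessions list of [session()] objects (at least one per group)
#' @param spec a [model_spec()] selecting the phase-specificity variant
#' @param config a [task_config()]
#' @param mcmc an [mcmc_control()]
#' @param priors a [prior_control()]
#' @return an object of class `rl_posterior`: list with `samples`
#'   (iterations x chains x parameters array, raw and derived natural-scale
#'   parameters), `pointwise_loglik` ((chains*draws) x trials matrix),
#'   `diagnostics` (data frame with `rhat` and `ess`), `spec`, `groups`,
#'   `animals`, `trial_map`, `sessions`, `config`, `mcmc`, `priors`
#' @export
fit_hierarchical <- function(sessions, spec = model_spec("full"),
                             config = task_config(), mcmc = mcmc_control(),
                             priors = prior_control()) {
  stopifnot(inherits(spec, "model_spec"), inherits(mcmc, "mcmc_control"))
  pk <- pack_sessions(sessions, config)
  chains <- vector("list", mcmc$chains)
  for (ch in seq_len(mcmc$chains)) {
    chain_seed <- (mcmc$seed %% 100000L) * 10000L + ch * 7919L
    chains[[ch]] <- rl_mcmc_chain(
      pk$choice, pk$reward, pk$phase, pk$offsets, pk$group_idx,
      length(pk$groups), config$n_odors, config$reward_magnitude,
      config$carry_over_values, spec$alpha_phase_specific,
      spec$beta_phase_specific, mcmc$warmup, mcmc$draws, chain_seed,
      unclass(priors))
  }
  Pa <- chains[[1L]]$Pa; Pb <- chains[[1L]]$Pb
  rn <- raw_param_names(pk$groups, pk$animals$mouse_id, Pa, Pb, config$n_odors)
  full <- lapply(chains, function(cc) {
    raw <- cc$samples
    colnames(raw) <- rn
    cbind(raw, derive_chain(raw, pk, Pa, Pb, config$n_odors))
  })
  pars <- colnames(full[[1L]])
  samples <- array(NA_real_, dim = c(mcmc$draws, mcmc$chains, length(pars)),
                   dimnames = list(NULL, paste0("chain", seq_len(mcmc$chains)),
                                   pars))
  for (ch in seq_len(mcmc$chains)) samples[, ch, ] <- full[[ch]]
  pointwise <- do.call(rbind, lapply(chains, `[[`, "pointwise"))
  diag <- mcmc_diagnostics(samples)
  keypat <- "^(mu_|sigma_|alpha_grp|beta_grp|delta_|v\\[)"
  key <- diag[grepl(keypat, diag$parameter) & !is.na(diag$rhat), ]
  bad <- key$parameter[key$rhat > mcmc$rhat_warn | key$ess < mcmc$ess_warn]
  if (length(bad))
    warning("possible non-convergence (rhat > ", mcmc$rhat_warn,
            " or ess < ", mcmc$ess_warn, "): ",
            paste(utils::head(bad, 8L), collapse = ", "),
            if (length(bad) > 8L) ", ..." else "")
  structure(
    list(samples = samples, pointwise_loglik = pointwise,
         diagnostics = diag, spec = spec, groups = pk$groups,
         animals = pk$animals, trial_map = pk$trial_map,
         sessions = sessions, config = config, mcmc = mcmc,
         priors = priors),
    class = "rl_posterior")
}

#' @export
print.rl_posterior <- function(x, ...) {
  d <- dim(x$samples)
  cat(sprintf("<rl_posterior> model '%s': %d animals in %d group(s)\n",
              x$spec$name, nrow(x$animals), length(x$groups)))
  cat(sprintf("  %d draws x %d chains; %d parameters; max rhat %.3f\n",
              d[1L], d[2L], d[3L], max(x$diagnostics$rhat, na.rm = TRUE)))
  invisible(x)
}

# Flattened draws (chains stacked) of one named parameter.
posterior_draws <- function(post, parameter) {
  if (!parameter %in% dimnames(post$samples)[[3L]])
    stop("unknown parameter: ", parameter)
  as.vector(post$samples[, , parameter])
}

#' Credible-interval contrast of a group-level parameter
#'
#' Computes, per posterior draw, the difference (group_a minus group_b) of a
#' natural-scale group-level quantity, and reports the central credible
#' interval at the requested level. The phase changes `delta_alpha` and
#' `delta_beta` are evaluated per draw (test minus acquisition) before
#' differencing. A difference is conventionally called significant when the
#' interval excludes 0.
#'
#' @param post an [fit_hierarchical()] posterior
#' @param parameter one of `"alpha_acq"`, `"alpha_test"`, `"beta_acq"`,
#'   `"beta_test"`, `"delta_alpha"`, `"delta_beta"`
#' @param group_a,group_b group labels present in the posterior
#' @param level credible level (default 0.95)
#' @return an object of class `group_contrast` with `ci_low`, `ci_high`,
#'   `median`, `prob_positive`, `excludes_zero` and the per-draw differences
#' @export
contrast_groups <- function(post, parameter, group_a, group_b, level = 0.95) {
  stopifnot(inherits(post, "rl_posterior"), level > 0, level < 1)
  if (!all(c(group_a, group_b) %in% post$groups))
    stop("unknown group label; posterior has: ",
         paste(post$groups, collapse = ", "))
  col_for <- function(g) {
    switch(parameter,
           alpha_acq = sprintf("alpha_grp[%s,acq]", g),
           alpha_test = sprintf("alpha_grp[%s,test]", g),
           beta_acq = sprintf("beta_grp[%s,acq]", g),
           beta_test = sprintf("beta_grp[%s,test]", g),
           delta_alpha = sprintf("delta_alpha_grp[%s]", g),
           delta_beta = sprintf("delta_beta_grp[%s]", g),
           stop("unknown parameter: ", parameter))
  }
  d <- posterior_draws(post, col_for(group_a)) -
    posterior_draws(post, col_for(group_b))
  qs <- stats::quantile(d, c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE)
  structure(
    list(parameter = parameter, group_a = group_a, group_b = group_b,
         level = level, ci_low = qs[1L], ci_high = qs[2L],
         median = stats::median(d), prob_positive = mean(d > 0),
         excludes_zero = qs[1L] > 0 || qs[2L] < 0, draws = d),
    class = "group_contrast")
}

#' @export
print.group_contrast <- function(x, ...) {
  cat(sprintf("<group_contrast> %s: %s - %s\n", x$parameter, x$group_a,
              x$group_b))
  cat(sprintf("  median %.4g, %d%% CI [%.4g, %.4g]%s\n", x$median,
              round(100 * x$level), x$ci_low, x$ci_high,
              if (x$excludes_zero) " (excludes 0)" else ""))
  invisible(x)
}

#' Posterior-predictive check on choices to criterion
#'
#' For each fitted animal, takes its posterior-mean phase-specific
#' parameters and the posterior-mean shared initial values, simulates the
#' full task `n_sims_per_animal` times (no omissions, criterion-terminated
#' phases), and reports the mean simulated choices to criterion per phase
#' next to the observed value.
#'
#' @param post an [fit_hierarchical()] posterior
#' @param config a [task_config()]; defaults to the fit's configuration
#' @param n_sims_per_animal simulations per animal (study setting: 100)
#' @param seed RNG seed
#' @param max_trials per-phase trial cap for the simulations
#' @return data frame with one row per animal x phase: `observed`,
#'   `observed_censored`, `simulated_mean`
#' @export
posterior_predictive_ctc <- function(post, config = post$config,
                                     n_sims_per_animal = 100L, seed = 1L,
                                     max_trials = 150L) {
  stopifnot(inherits(post, "rl_posterior"))
  pm <- apply(post$samples, 3L, mean)
  v <- initial_values(pm[sprintf("v[%d]", seq_len(config$n_odors))])
  rows <- list()
  with_seed(seed, {
    for (k in seq_len(nrow(post$animals))) {
      id <- post$animals$mouse_id[k]
      pars <- rl_params(
        alpha_acq = pm[sprintf("alpha[%s,acq]", id)],
        alpha_test = pm[sprintf("alpha[%s,test]", id)],
        beta_acq = pm[sprintf("beta[%s,acq]", id)],
        beta_test = pm[sprintf("beta[%s,test]", id)])
      ag <- agent_spec(pars, v, omission_prob = 0, group = post$animals$group[k],
                       mouse_id = id)
      sims <- matrix(NA_real_, n_sims_per_animal, 2L)
      for (s in seq_len(n_sims_per_animal)) {
        ss <- simulate_session(ag, config, max_trials = max_trials)
        for (p in 1:2)
          sims[s, p] <- choices_to_criterion(ss, task_phases()[p], config)$choices
      }
      obs_sess <- post$sessions[[k]]
      for (p in 1:2) {
        ph <- task_phases()[p]
        obs <- choices_to_criterion(obs_sess, ph, config)
        rows[[length(rows) + 1L]] <- data.frame(
          mouse_id = id, group = post$animals$group[k], phase = ph,
          observed = obs$choices, observed_censored = obs$censored,
          simulated_mean = mean(sims[, p]), stringsAsFactors = FALSE)
      }
    }
  })
  do.call(rbind, rows)
}
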