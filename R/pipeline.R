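# End-to-end analysis pipeline: simulate (or read) sessions, fit model
# variants, rank by WAIC, contrast groups, posterior-predictive check,
# summarize behavior, and (optionally) score rotation-bias tracks.

#' Assemble a pipeline configuration
#'
#' @param seed master seed, recorded in every output
#' @param groups group specifications for [simulate_cohort()]; ignored when
#'   `sessions_file` is given
#' @param sessions_file optional session CSV to analyse instead of simulating
#' @param models character vector of [model_spec()] names to fit and compare
#' @param group_pairs list of 2-vectors of group labels to contrast; `NULL`
#'   contrasts every pair
#' @param contrast_parameters parameters passed to [contrast_groups()]
#' @param mcmc an [mcmc_control()]
#' @param task a [task_config()]
#' @param n_sims_ppc posterior-predictive simulations per animal
#' @param pose_specs optional named list of [pose_spec()] objects to run
#'   through the rotation pipeline
#' @return list of class `pipeline_config`
#' @export
pipeline_config <- function(seed = 1L,
                            groups = NULL,
                            sessions_file = NULL,
                            models = c("full", "shared", "alpha_only",
                                       "beta_only"),
                            group_pairs = NULL,
                            contrast_parameters = c("delta_alpha",
                                                    "delta_beta"),
                            mcmc = mcmc_control(chains = 2L, warmup = 500L,
                                                draws = 500L, seed = seed),
                            task = task_config(),
                            n_sims_ppc = 100L,
                            pose_specs = NULL) {
  if (is.null(groups) && is.null(sessions_file))
    stop("need either group specifications to simulate or a sessions_file")
  structure(list(seed = as.integer(seed), groups = groups,
                 sessions_file = sessions_file, models = models,
                 group_pairs = group_pairs,
                 contrast_parameters = contrast_parameters, mcmc = mcmc,
                 task = task, n_sims_ppc = as.integer(n_sims_ppc),
                 pose_specs = pose_specs),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Scalar fields override [pipeline_config()] defaults; `mcmc` and `task`
#' sub-maps override [mcmc_control()] and [task_config()] fields.
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON file
#' @return a [pipeline_config()]
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  args <- list()
  for (nm in c("seed", "sessions_file", "models", "contrast_parameters",
               "n_sims_ppc"))
    if (!is.null(raw[[nm]])) args[[nm]] <- raw[[nm]]
  if (!is.null(raw$groups)) args$groups <- raw$groups
  if (!is.null(raw$group_pairs))
    args$group_pairs <- lapply(raw$group_pairs, unlist)
  if (!is.null(raw$mcmc))
    args$mcmc <- do.call(mcmc_control, raw$mcmc)
  if (!is.null(raw$task))
    args$task <- do.call(task_config, raw$task)
  do.call(pipeline_config, args)
}

# Cheap content stamp for provenance (not cryptographic).
config_stamp <- function(config) {
  s <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA, force = TRUE)
  sprintf("%08x", sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 97 + 1)) %%
            .Machine$integer.max)
}

#' Run the full analysis pipeline
#'
#' Stages, in order: obtain sessions (simulate a cohort or read a CSV),
#' summarize behavior, fit each requested model variant, rank variants by
#' WAIC, compute credible-interval group contrasts on the best variant,
#' posterior-predictive choices-to-criterion, and (optionally) rotation-bias
#' scoring of pose tracks. Every artifact is written under `out_dir` and
#' stamped with the seed and a configuration stamp.
#'
#' @param config a [pipeline_config()]
#' @param out_dir output directory (created if absent)
#' @param quiet suppress stage messages
#' @return (invisibly) list with the sessions, fits, WAIC table, contrasts,
#'   posterior-predictive table and output paths
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  task <- config$task

  say("[1/6] sessions")
  sessions <- if (!is.null(config$sessions_file)) {
    read_sessions(config$sessions_file, task, groups = NULL,
                  require_criterion = FALSE)
  } else {
    simulate_cohort(config$groups, task, seed = config$seed)
  }
  write_sessions(sessions, file.path(out_dir, "sessions.csv"))

  say("[2/6] behavior summaries")
  bs <- behavior_summary(sessions, task)
  utils::write.csv(bs, file.path(out_dir, "behavior_summary.csv"),
                   row.names = FALSE)

  fits <- list(); waic_tab <- NULL; contrasts <- list(); ppc <- NULL
  if (length(config$models)) {
    say("[3/6] fitting %d model variant(s)", length(config$models))
    for (m in config$models)
      fits[[m]] <- fit_hierarchical(sessions, model_spec(m), task,
                                    mcmc = config$mcmc)
    waic_tab <- waic_compare(fits)
    jsonlite::write_json(waic_tab, file.path(out_dir, "waic.json"),
                         auto_unbox = TRUE, digits = NA)
    best <- fits[[waic_tab$model[1L]]]
    utils::write.csv(best$diagnostics,
                     file.path(out_dir, "diagnostics.csv"),
                     row.names = FALSE)

    say("[4/6] group contrasts (best model: %s)", waic_tab$model[1L])
    grs <- best$groups
    pairs <- config$group_pairs %||%
      (if (length(grs) > 1L) utils::combn(grs, 2L, simplify = FALSE) else list())
    for (pr in pairs) {
      for (par in config$contrast_parameters) {
        ct <- contrast_groups(best, par, pr[1L], pr[2L])
        ct$draws <- NULL
        contrasts[[sprintf("%s:%s_vs_%s", par, pr[1L], pr[2L])]] <-
          unclass(ct)
      }
    }
    jsonlite::write_json(contrasts, file.path(out_dir, "contrasts.json"),
                         auto_unbox = TRUE, digits = NA)

    say("[5/6] posterior-predictive choices to criterion")
    ppc <- posterior_predictive_ctc(best, task,
                                    n_sims_per_animal = config$n_sims_ppc,
                                    seed = config$seed)
    utils::write.csv(ppc, file.path(out_dir, "ppc_ctc.csv"),
                     row.names = FALSE)
  }

  rotation <- NULL
  if (!is.null(config$pose_specs)) {
    say("[6/6] rotation-bias scoring")
    rotation <- lapply(config$pose_specs, function(ps) {
      r <- analyze_rotation(simulate_pose_track(ps))
      list(bias = r$bias, net_rotation_rate = r$net_rotation_rate,
           n_moving = r$n_moving)
    })
    jsonlite::write_json(rotation, file.path(out_dir, "rotation.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  info <- list(seed = config$seed, config_stamp = config_stamp(config),
               models = config$models,
               n_sessions = length(sessions),
               timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(info, file.path(out_dir, "run_info.json"),
                       auto_unbox = TRUE)
  invisible(list(sessions = sessions, fits = fits, waic = waic_tab,
                 contrasts = contrasts, ppc = ppc, rotation = rotation,
                 behavior = bs, out_dir = out_dir))
}
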