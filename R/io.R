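# Trial-table and covariate I/O, session assembly, and the end-to-end
# pipeline with a run manifest.

trial_columns <- c("subject_id", "session", "drug", "trial", "phase",
                   "choice_role", "outcome")

#' Write / read the tidy trial-table CSV
#'
#' One row per trial with columns `subject_id`, `session`, `drug`, `trial`,
#' `phase`, `choice_role`, `outcome` and optionally `rt_ms`. Reading
#' validates every row and reports the offending rows on violation;
#' `write_trials` followed by `read_trials` is the identity on valid data.
#'
#' @param trials Trial table.
#' @param path File path.
#' @return `read_trials` returns the validated data.frame; `write_trials`
#'   returns `path` invisibly.
#' @export
write_trials <- function(trials, path) {
  check_trials_df(trials)
  write.csv(trials, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  trials <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(trial_columns, names(trials))
  if (length(missing))
    stop("trial table lacks columns: ", paste(missing, collapse = ", "))
  bad <- which(!trials$outcome %in% c(-1, 1))
  if (length(bad))
    stop("outcome must be -1 or +1; offending rows: ",
         paste(head(bad, 5L), collapse = ", "))
  bad <- which(!trials$drug %in% c("placebo", "MPH"))
  if (length(bad))
    stop("unknown drug label; offending rows: ",
         paste(head(bad, 5L), collapse = ", "))
  bad <- which(!trials$phase %in% c("acquisition", "reversal"))
  if (length(bad))
    stop("unknown phase label; offending rows: ",
         paste(head(bad, 5L), collapse = ", "))
  key <- paste(trials$subject_id, trials$session, trials$trial)
  if (anyDuplicated(key))
    stop("duplicate (subject, session, trial) rows: ",
         paste(head(key[duplicated(key)], 3L), collapse = "; "))
  if ("rt_ms" %in% names(trials) && any(trials$rt_ms <= 0, na.rm = TRUE))
    stop("reaction times must be positive")
  trials$session <- as.integer(trials$session)
  trials$trial <- as.integer(trials$trial)
  trials
}

#' Write / read the subject covariate CSV
#'
#' Columns `subject_id`, `wm_span` (listening-span working-memory total
#' score), `bis` (BIS-11 impulsivity total score).
#'
#' @param subjects Covariate table.
#' @param path File path.
#' @export
write_subjects <- function(subjects, path) {
  stopifnot(all(c("subject_id", "wm_span", "bis") %in% names(subjects)))
  write.csv(subjects, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_subjects
#' @export
read_subjects <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  subjects <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("subject_id", "wm_span", "bis"), names(subjects))
  if (length(missing))
    stop("subject table lacks columns: ", paste(missing, collapse = ", "))
  if (anyDuplicated(subjects$subject_id)) stop("duplicate subject ids")
  subjects
}

#' Assemble per-subject session lists from a trial table
#'
#' @param trials Trial table.
#' @param config A [task_config()].
#' @return Named list (by subject) of lists of [prl_session()]s, ordered
#'   placebo first.
#' @export
sessions_from_trials <- function(trials, config = task_config()) {
  check_trials_df(trials)
  roles <- task_roles(config)
  out <- lapply(split(trials, trials$subject_id), function(sub) {
    sess <- lapply(split(sub, sub$drug), function(d) {
      d <- d[order(d$trial), ]
      prl_session(match(d$choice_role, roles), d$outcome,
                  drug = d$drug[1L], config = config,
                  subject_id = d$subject_id[1L],
                  rt_ms = if ("rt_ms" %in% names(d)) d$rt_ms else NULL)
    })
    sess[order(names(sess) != "placebo")]
  })
  out[order(names(out))]
}

#' Run the full analysis pipeline
#'
#' Executes, in order: fast-RT filtering, behavioural statistics
#' (chance-corrected accuracy, stay probabilities, the Valence x Phase x
#' Drug ANCOVA with covariates and its phase-wise simple effects), base-model
#' comparison by HBI, drug-model comparison by HBI, non-hierarchical
#' parameter inference with the drug-change statistics,
#' posterior-predictive validation of the winning drug model, and the
#' optimal-learning-rate analysis for the 3- and 2-option task variants. All
#' tables are written as CSV/JSON under `out_dir` together with a run
#' manifest recording seeds, inputs and stages.
#'
#' @param trials Trial table (e.g. from [generate_cohort()] or
#'   [read_trials()]).
#' @param subjects Covariate table.
#' @param out_dir Output directory (created if needed).
#' @param config A [task_config()].
#' @param seed Master seed for every stochastic stage.
#' @param base_models,drug_models Model-name vectors for the two comparisons.
#' @param n_restarts Optimisation restarts per subject fit.
#' @param n_agents Posterior-predictive agents per subject-session.
#' @param lr_n_sims Simulations per grid point of the learning-rate curves.
#' @return Invisibly, a list with every stage's result.
#' @export
run_pipeline <- function(trials, subjects, out_dir, config = task_config(),
                         seed = 1L,
                         base_models = c("EWA", "EWA+F", "Hybrid",
                                         "Hybrid+F"),
                         drug_models = c("EWA+F", "EWA+F+dphi", "EWA+F+drho",
                                         "EWA+F+dalpha_f", "EWA+F+dbeta"),
                         n_restarts = 5L, n_agents = 100L,
                         lr_n_sims = 200L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(command = "run_pipeline", seed = seed,
                   package_version = as.character(packageVersion("revlearn3")),
                   n_subjects = length(unique(trials$subject_id)),
                   started = format(Sys.time()), stages = character(0))
  write_manifest <- function() jsonlite::write_json(
    manifest, file.path(out_dir, "manifest.json"), auto_unbox = TRUE,
    pretty = TRUE)
  stage <- function(name) {
    manifest$stages <<- c(manifest$stages, name)
    write_manifest()
  }
  write_manifest()
  res <- list()

  stage("filter_fast_rt")
  filt <- suppressWarnings(filter_fast_rt(trials))
  res$n_excluded <- filt$n_excluded

  stage("behaviour_stats")
  res$accuracy <- accuracy_metrics(filt$trials, config)
  res$stay <- stay_probabilities(filt$trials)
  covs <- subjects[, c("subject_id", "wm_span", "bis")]
  res$anova <- rm_anova(res$accuracy, covs)
  res$simple_effects_phase <- simple_effects(res$accuracy, covs, "phase")
  write.csv(res$accuracy, file.path(out_dir, "accuracy.csv"),
            row.names = FALSE)
  write.csv(res$stay, file.path(out_dir, "stay_probabilities.csv"),
            row.names = FALSE)
  write.csv(res$anova, file.path(out_dir, "anova.csv"), row.names = FALSE)

  data <- sessions_from_trials(filt$trials, config)

  stage("base_model_hbi")
  res$hbi_base <- hbi(lapply(base_models, prl_model), data,
                      n_restarts = n_restarts, seed = seed + 1L)
  stage("drug_model_hbi")
  res$hbi_drug <- hbi(lapply(drug_models, prl_model), data,
                      n_restarts = n_restarts, seed = seed + 2L)
  comparison <- rbind(
    data.frame(family = "base", model = res$hbi_base$model_names,
               frequency = res$hbi_base$frequencies, xp = res$hbi_base$xp,
               bor = res$hbi_base$bor, pxp = res$hbi_base$pxp),
    data.frame(family = "drug", model = res$hbi_drug$model_names,
               frequency = res$hbi_drug$frequencies, xp = res$hbi_drug$xp,
               bor = res$hbi_drug$bor, pxp = res$hbi_drug$pxp))
  write.csv(comparison, file.path(out_dir, "model_comparison.csv"),
            row.names = FALSE)

  stage("parameter_inference")
  winner <- res$hbi_drug$model_names[which.max(res$hbi_drug$pxp)]
  infer_model <- if (grepl("\\+d", winner)) winner else "EWA+F+dphi"
  fits <- fit_subjects(prl_model(infer_model), data,
                       n_restarts = n_restarts, seed = seed + 3L)
  res$parameters <- extract_subject_parameters(fits)
  split_par <- prl_model(infer_model)$split_param
  res$param_change <- parameter_change_stats(res$parameters, covs,
                                             accuracy = res$accuracy,
                                             param = split_par)
  write.csv(res$parameters, file.path(out_dir, "subject_parameters.csv"),
            row.names = FALSE)

  stage("posterior_predictive")
  res$ppc <- posterior_predictive(fits, prl_model(infer_model), config,
                                  n_agents = n_agents, seed = seed + 4L)
  res$ppc_anova <- rm_anova(res$ppc$accuracy, covs)
  write.csv(res$ppc$accuracy, file.path(out_dir, "ppc_accuracy.csv"),
            row.names = FALSE)
  write.csv(res$ppc_anova, file.path(out_dir, "ppc_anova.csv"),
            row.names = FALSE)

  stage("optimal_learning_rate")
  ref <- res$parameters
  reference_params <- c(rho = median(ref$rho), beta = median(ref$beta),
                        alpha_f = median(ref$alpha_f))
  res$lr_curve_3opt <- optimal_learning_rate_curve(
    config, reference_params, n_sims = lr_n_sims, seed = seed + 5L)
  res$lr_curve_2opt <- optimal_learning_rate_curve(
    task_config(n_options = 2L), reference_params, n_sims = lr_n_sims,
    seed = seed + 6L)
  write.csv(as.data.frame(res$lr_curve_3opt),
            file.path(out_dir, "lr_curve_3opt.csv"), row.names = FALSE)
  write.csv(as.data.frame(res$lr_curve_2opt),
            file.path(out_dir, "lr_curve_2opt.csv"), row.names = FALSE)

  summary <- list(
    n_excluded_fast_rt = res$n_excluded,
    anova_phase_drug_wm = as.list(
      res$anova[res$anova$effect == "Phase:Drug:wm_span",
                c("F", "df1", "df2", "p")]),
    base_winner = res$hbi_base$model_names[which.max(res$hbi_base$pxp)],
    base_pxp = max(res$hbi_base$pxp),
    drug_winner = winner, drug_pxp = max(res$hbi_drug$pxp),
    t_test = res$param_change$t_test,
    spearman_wm = res$param_change$spearman_wm,
    spearman_performance = res$param_change$spearman_performance[
      c("rho", "p")],
    phi_opt_3opt = attr(res$lr_curve_3opt, "phi_opt"),
    phi_opt_2opt = attr(res$lr_curve_2opt, "phi_opt"))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  manifest$finished <- format(Sys.time())
  write_manifest()
  invisible(res)
}
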