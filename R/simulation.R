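# Agent simulation, posterior-predictive model validation and the
# optimal-learning-rate analysis.

# named constrained parameter vector -> 4-slot vector for the compiled
# simulator: (phi|eta, rho|kappa, beta, alpha_f)
sim_param_slots <- function(kind, params) {
  need <- if (kind == "ewa") c("phi", "rho", "beta") else
    c("eta", "kappa", "beta")
  if (!all(need %in% names(params)))
    stop(sprintf("params must name %s", paste(need, collapse = ", ")))
  af <- if ("alpha_f" %in% names(params)) params[["alpha_f"]] else 0
  slots <- c(params[[need[1L]]], params[[need[2L]]], params[["beta"]], af)
  if (any(!is.finite(slots)) || any(slots[c(1, 2, 4)] < 0) ||
      any(slots[c(1, 2, 4)] > 1) || slots[3] < 0)
    stop("parameters violate their constraints")
  slots
}

#' Simulate one agent playing the task
#'
#' Plays a model against a feedback schedule: the first trial's choice
#' defines the roles (so in role coordinates the first choice is "RP", per
#' the task's first-choice assignment rule), later choices are sampled from
#' the softmax over the model's own value trajectory.
#'
#' @param model A [prl_model()] or base-family model name. Split models
#'   cannot be simulated directly — simulate each session with its own
#'   parameter values instead.
#' @param params Named constrained parameters (`phi`, `rho`, `beta` and
#'   optionally `alpha_f`; `eta`, `kappa` for hybrid models).
#' @param config A [task_config()].
#' @param seed Optional seed (covers schedule generation and choices).
#' @param schedule Optional pre-generated [generate_feedback_schedule()];
#'   generated from `config` otherwise.
#' @param drug,subject_id Labels attached to the returned session.
#' @return A `prl_session`.
#' @export
simulate_agent <- function(model, params, config = task_config(),
                           seed = NULL, schedule = NULL, drug = "placebo",
                           subject_id = NA) {
  if (is.character(model)) model <- prl_model(model)
  if (!is.null(model$split_param))
    stop("simulate split models one session at a time with explicit per-session parameters")
  slots <- sim_param_slots(model$kind, params)
  with_seed(seed, {
    if (is.null(schedule)) schedule <- generate_feedback_schedule(config)
    sim <- simulate_session_cpp(schedule$outcomes, model$model_code, slots)
    prl_session(sim$choices, sim$outcomes, drug = drug, config = config,
                subject_id = subject_id)
  })
}

# mean choice-proportion matrix over n_agents fresh simulations
simulate_choice_probs <- function(model_code, slots, config, n_agents) {
  schedule <- generate_feedback_schedule(config)
  simulate_agents_cpp(schedule$outcomes, model_code, slots, n_agents)
}

#' Posterior-predictive simulation of a fitted cohort
#'
#' The standard model-validation step: for every subject and session, a
#' number of artificial agents play the task with that subject's fitted
#' parameters, and their choices are averaged to represent the subject's
#' behaviour. The averaged trial-wise choice probabilities are re-analysed
#' exactly like real data: the returned accuracy table feeds [rm_anova()].
#'
#' @param fits List of `subject_fit`s (one per subject) for a single model —
#'   base or drug-split; split parameters are routed to the matching session.
#' @param model The [prl_model()] the fits belong to.
#' @param config A [task_config()].
#' @param n_agents Agents per subject-session (default 100).
#' @param seed Seed for schedules and choices.
#' @param drugs Session labels simulated per subject.
#' @return A list with `probs` (per subject, per drug: trial x role
#'   choice-probability matrix) and `accuracy` (chance-corrected accuracy
#'   table in the same format as [accuracy_metrics()]).
#' @export
posterior_predictive <- function(fits, model, config = task_config(),
                                 n_agents = 100L, seed = NULL,
                                 drugs = c("placebo", "MPH")) {
  if (is.character(model)) model <- prl_model(model)
  stopifnot(length(fits) >= 1L, n_agents >= 1L,
            all(vapply(fits, inherits, logical(1), "subject_fit")))
  roles <- task_roles(config)
  with_seed(seed, {
    probs <- lapply(fits, function(f) {
      per_drug <- lapply(drugs, function(dr) {
        p <- constrained_params(model, f$par, drug = dr)
        slots <- c(p[[1L]], p[[2L]], p[["beta"]], p[["alpha_f"]])
        pm <- simulate_choice_probs(model$model_code, slots, config, n_agents)
        colnames(pm) <- roles
        pm
      })
      setNames(per_drug, drugs)
    })
    names(probs) <- vapply(fits, function(f) as.character(f$subject_id),
                           character(1))
    acc <- do.call(rbind, lapply(names(probs), function(sid) {
      do.call(rbind, lapply(drugs, function(dr) {
        pm <- probs[[sid]][[dr]]
        ph <- trial_phase(config, seq_len(nrow(pm)))
        do.call(rbind, lapply(c("acquisition", "reversal"), function(phase) {
          sel <- colMeans(pm[ph == phase, , drop = FALSE])
          rewarded <- current_rewarded_role(phase)
          punished <- current_punished_role(phase)
          data.frame(subject_id = sid, drug = dr, phase = phase,
                     pReward = sel[[rewarded]], pPunish = sel[[punished]],
                     pNeutral = if ("NN" %in% roles) sel[["NN"]] else NA_real_)
        }))
      }))
    }))
    acc <- add_corrected_accuracy(acc)
    list(probs = probs, accuracy = acc)
  })
}

# Smooth peak location: vertex of a quadratic fitted in a window around the
# grid argmax, clipped to the grid. Far more stable against Monte-Carlo
# noise than the raw argmax when the curve is flat near its maximum.
smooth_peak <- function(phi, acc, i_max, window = 0.06) {
  keep <- abs(phi - phi[i_max]) <= window + 1e-9
  if (sum(keep) < 3L) return(phi[i_max])
  cf <- coef(lm(acc[keep] ~ poly(phi[keep], 2, raw = TRUE)))
  if (!is.finite(cf[3L]) || cf[3L] >= 0) return(phi[i_max])
  min(max(-cf[2L] / (2 * cf[3L]), min(phi)), max(phi))
}

#' Accuracy as a function of the inverse learning rate
#'
#' Sweeps the inverse learning rate `phi` of EWA(+F) agents over a grid, with
#' the remaining parameters fixed at reference values, and records
#' Monte-Carlo mean task accuracy (probability of choosing the currently
#' mostly-rewarded stimulus) and mean reward per trial. Used to compare the
#' accuracy-maximising learning rate between the 3-option task and the
#' matched 2-option 70:30 predecessor design.
#'
#' @param config A [task_config()] (3- or 2-option).
#' @param reference_params Named constrained values for `rho`, `beta` and
#'   `alpha_f` (defaults: typical winning-model group medians for this
#'   paradigm).
#' @param phi_grid Grid of `phi` values in `[0, 1]`.
#' @param n_sims Simulated sessions per grid point (>= 100; each gets a fresh
#'   schedule).
#' @param seed Seed.
#' @return An `lr_curve` data.frame with columns `phi`, `accuracy`,
#'   `accuracy_se`, `reward`, `reward_se`; attributes `phi_opt` (accuracy
#'   argmax), `phi_opt_smooth` (vertex of a quadratic fitted around the
#'   argmax — robust when the curve is flat near its maximum),
#'   `phi_opt_reward`, `phi_flat` (grid values within one standard error of
#'   the maximum), and `label`.
#' @export
optimal_learning_rate_curve <- function(config = task_config(),
                                        reference_params = c(rho = 0.63,
                                                             beta = 4.23,
                                                             alpha_f = 0.35),
                                        phi_grid = seq(0, 1, by = 0.05),
                                        n_sims = 200L, seed = NULL) {
  stopifnot(length(phi_grid) >= 1L, all(phi_grid >= 0), all(phi_grid <= 1),
            n_sims >= 100L)
  if (length(phi_grid) == 0L) stop("phi_grid is empty")
  ph <- trial_phase(config)
  rewarded <- ifelse(ph == "acquisition", "RP", "PR")
  with_seed(seed, {
    rows <- lapply(phi_grid, function(phi) {
      slots <- sim_param_slots("ewa", c(phi = phi, reference_params))
      acc <- rew <- numeric(n_sims)
      for (i in seq_len(n_sims)) {
        schedule <- generate_feedback_schedule(config)
        sim <- simulate_session_cpp(schedule$outcomes, 1L, slots)
        chosen <- task_roles(config)[sim$choices]
        acc[i] <- mean(chosen == rewarded)
        rew[i] <- mean(sim$outcomes)
      }
      data.frame(phi = phi, accuracy = mean(acc),
                 accuracy_se = sd(acc) / sqrt(n_sims),
                 reward = mean(rew), reward_se = sd(rew) / sqrt(n_sims))
    })
    curve <- do.call(rbind, rows)
    i_max <- which.max(curve$accuracy)
    flat <- curve$phi[curve$accuracy >=
                        curve$accuracy[i_max] - curve$accuracy_se[i_max]]
    structure(curve, class = c("lr_curve", "data.frame"),
              phi_opt = curve$phi[i_max],
              phi_opt_smooth = smooth_peak(curve$phi, curve$accuracy, i_max),
              phi_opt_reward = curve$phi[which.max(curve$reward)],
              phi_flat = flat,
              label = sprintf("%d-option task", config$n_options))
  })
}

#' @export
print.lr_curve <- function(x, ...) {
  cat(sprintf("<lr_curve> %s: accuracy-optimal phi = %.2f (smoothed %.3f, flat region %.2f-%.2f), reward-optimal phi = %.2f\n",
              attr(x, "label"), attr(x, "phi_opt"), attr(x, "phi_opt_smooth"),
              min(attr(x, "phi_flat")), max(attr(x, "phi_flat")),
              attr(x, "phi_opt_reward")))
  NextMethod()
}
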