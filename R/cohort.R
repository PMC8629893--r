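# Study-shaped synthetic cohorts with known ground truth: EWA+F agents whose
# inverse learning rate changes under the drug as a function of
# working-memory span.

#' Specify a synthetic cohort
#'
#' Defaults emulate a full-scale cohort for this paradigm: 102 subjects,
#' two 80-trial
#' sessions (placebo and MPH, order counterbalanced 50/52), EWA+F generating
#' parameters drawn from independent Gaussians on the unconstrained scale
#' whose constrained medians sit at the winning-model group medians
#' (phi 0.77, rho 0.63, beta 4.23, alpha_f 0.35), and a drug effect on the
#' unconstrained inverse learning rate,
#' `delta_phi = b * z(wm) + noise_sd * epsilon`, so the MPH-session phi
#' covaries with working-memory span. The default effect size (`b = 0.4`,
#' `noise_sd = 1`) was calibrated by pilot recovery runs so that the fitted
#' delta-phi vs WM Spearman correlation lands near 0.2 at n = 102, a
#' realistic magnitude for covariate-dependent drug effects.
#'
#' @param n_subjects Cohort size (>= 2).
#' @param config A [task_config()].
#' @param group_median Named constrained-scale medians of `phi`, `rho`,
#'   `beta`, `alpha_f`.
#' @param group_sd Named unconstrained-scale group standard deviations.
#' @param b Drug-effect slope on the unconstrained phi per WM z-score.
#' @param noise_sd Subject-level noise of the drug effect (>= 0).
#' @param wm_mean,wm_sd,wm_range Integer listening-span score distribution.
#' @param bis_mean,bis_sd,bis_range Integer BIS-11 total score distribution.
#' @param n_mph_first Subjects receiving MPH in session 1 (default 50 when
#'   `n_subjects` is 102, else half).
#' @param rt_mode `"uniform"` draws reaction times uniformly from `rt_range`
#'   (so a small fraction falls under the 200 ms filter); `"none"` omits
#'   them.
#' @param rt_range RT range in ms.
#' @return A `cohort_spec` object.
#' @export
cohort_spec <- function(n_subjects = 102L, config = task_config(),
                        group_median = c(phi = 0.77, rho = 0.63,
                                         beta = 4.23, alpha_f = 0.35),
                        group_sd = c(phi = 0.8, rho = 0.8,
                                     beta = 0.5, alpha_f = 0.8),
                        b = 0.4, noise_sd = 1,
                        wm_mean = 42, wm_sd = 12, wm_range = c(10, 80),
                        bis_mean = 63, bis_sd = 9, bis_range = c(30, 114),
                        n_mph_first = NULL, rt_mode = c("uniform", "none"),
                        rt_range = c(150, 2000)) {
  rt_mode <- match.arg(rt_mode)
  n_subjects <- as.integer(n_subjects)
  stopifnot(n_subjects >= 2L, inherits(config, "task_config"),
            noise_sd >= 0, all(group_sd > 0),
            all(c("phi", "rho", "beta", "alpha_f") %in% names(group_median)))
  stopifnot(all(group_median[c("phi", "rho", "alpha_f")] > 0),
            all(group_median[c("phi", "rho", "alpha_f")] < 1),
            group_median[["beta"]] > 0)
  if (is.null(n_mph_first))
    n_mph_first <- if (n_subjects == 102L) 50L else n_subjects %/% 2L
  stopifnot(n_mph_first >= 0L, n_mph_first <= n_subjects)
  group_mean_u <- c(logit(group_median[["phi"]]),
                    logit(group_median[["rho"]]),
                    log(group_median[["beta"]]),
                    logit(group_median[["alpha_f"]]))
  names(group_mean_u) <- c("phi", "rho", "beta", "alpha_f")
  structure(
    list(n_subjects = n_subjects, config = config,
         group_median = group_median, group_mean_u = group_mean_u,
         group_sd = group_sd[c("phi", "rho", "beta", "alpha_f")],
         b = b, noise_sd = noise_sd,
         wm_mean = wm_mean, wm_sd = wm_sd, wm_range = wm_range,
         bis_mean = bis_mean, bis_sd = bis_sd, bis_range = bis_range,
         n_mph_first = as.integer(n_mph_first), rt_mode = rt_mode,
         rt_range = rt_range),
    class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("<cohort_spec> %d subjects x 2 sessions x %d trials, b = %g, noise_sd = %g\n",
              x$n_subjects, x$config$n_trials, x$b, x$noise_sd))
  invisible(x)
}

rint_clamped <- function(n, mean, sd, range) {
  pmin(pmax(round(rnorm(n, mean, sd)), range[1L]), range[2L])
}

#' Generate a synthetic cohort with ground truth
#'
#' Draws subject covariates and generating parameters, simulates both
#' sessions per subject with EWA+F (MPH sessions use
#' `phi_u + delta_phi` on the unconstrained scale, so constraints are never
#' violated), and returns the study-shaped trial table, the subject covariate
#' table, and the generating truth for recovery analyses. Identical
#' spec + seed give identical datasets.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer master seed.
#' @return A `prl_cohort` list: `trials` (one row per trial), `subjects`
#'   (`subject_id`, `wm_span`, `bis`, `mph_first`), `truth` (per-subject
#'   generating parameters, unconstrained and constrained, `delta_phi_u`,
#'   `wm_z`), `spec`, `seed`.
#' @export
generate_cohort <- function(spec, seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  cfg <- spec$config
  with_seed(seed, {
    n <- spec$n_subjects
    subjects <- data.frame(
      subject_id = sprintf("s%03d", seq_len(n)),
      wm_span = rint_clamped(n, spec$wm_mean, spec$wm_sd, spec$wm_range),
      bis = rint_clamped(n, spec$bis_mean, spec$bis_sd, spec$bis_range),
      mph_first = seq_len(n) %in% sample.int(n, spec$n_mph_first))
    wm_z <- as.vector(scale(subjects$wm_span))
    pu <- sapply(c("phi", "rho", "beta", "alpha_f"), function(p)
      rnorm(n, spec$group_mean_u[[p]], spec$group_sd[[p]]))
    delta_phi <- spec$b * wm_z + spec$noise_sd * rnorm(n)
    if (any(!is.finite(pu)) || any(!is.finite(delta_phi)))
      stop("generating distributions produced non-finite parameters")
    truth <- data.frame(
      subject_id = subjects$subject_id,
      phi_placebo_u = pu[, "phi"], phi_mph_u = pu[, "phi"] + delta_phi,
      rho_u = pu[, "rho"], beta_u = pu[, "beta"],
      alpha_f_u = pu[, "alpha_f"], delta_phi_u = delta_phi, wm_z = wm_z)
    truth$phi_placebo <- sigmoid(truth$phi_placebo_u)
    truth$phi_mph <- sigmoid(truth$phi_mph_u)
    truth$rho <- sigmoid(truth$rho_u)
    truth$beta <- exp(truth$beta_u)
    truth$alpha_f <- sigmoid(truth$alpha_f_u)

    tpt <- cfg$n_trials
    n_rows <- n * 2L * tpt
    col <- function(init) rep(init, n_rows)
    trials <- data.frame(
      subject_id = col(NA_character_), session = col(NA_integer_),
      drug = col(NA_character_), trial = col(NA_integer_),
      phase = col(NA_character_), choice_role = col(NA_character_),
      outcome = col(NA_real_), rt_ms = col(NA_real_))
    phase <- trial_phase(cfg)
    roles <- task_roles(cfg)
    row0 <- 0L
    for (i in seq_len(n)) {
      drugs <- if (subjects$mph_first[i]) c("MPH", "placebo")
               else c("placebo", "MPH")
      for (sess in 1:2) {
        dr <- drugs[sess]
        phi_u <- if (dr == "MPH") truth$phi_mph_u[i] else
          truth$phi_placebo_u[i]
        slots <- c(sigmoid(phi_u), truth$rho[i], truth$beta[i],
                   truth$alpha_f[i])
        schedule <- generate_feedback_schedule(cfg)
        sim <- simulate_session_cpp(schedule$outcomes, 1L, slots)
        idx <- row0 + seq_len(tpt)
        trials$subject_id[idx] <- subjects$subject_id[i]
        trials$session[idx] <- sess
        trials$drug[idx] <- dr
        trials$trial[idx] <- seq_len(tpt)
        trials$phase[idx] <- phase
        trials$choice_role[idx] <- roles[sim$choices]
        trials$outcome[idx] <- sim$outcomes
        if (spec$rt_mode == "uniform")
          trials$rt_ms[idx] <- runif(tpt, spec$rt_range[1L],
                                     spec$rt_range[2L])
        row0 <- row0 + tpt
      }
    }
    if (spec$rt_mode == "none") trials$rt_ms <- NULL
    structure(list(trials = trials, subjects = subjects, truth = truth,
                   spec = spec, seed = seed),
              class = "prl_cohort")
  })
}

#' @export
print.prl_cohort <- function(x, ...) {
  cat(sprintf("<prl_cohort> %d subjects, %d trial rows (seed %s)\n",
              nrow(x$subjects), nrow(x$trials), x$seed))
  invisible(x)
}
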