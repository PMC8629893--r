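#' Define the structure of the probabilistic reversal learning task
#'
#' The paradigm presents `n_options` stimuli on every trial; each stimulus has
#' a role with a phase-specific reward probability. In the default 3-option
#' design, the first-chosen stimulus ("RP") is rewarded on 75% of trials
#' during acquisition and 25% after the reversal, role "PR" has the mirrored
#' contingency, and the neutral role "NN" is rewarded on 50% of trials
#' throughout. Contingencies flip at `reversal_trial` (1-based: the default 41
#' means trials 1-40 are acquisition and 41-80 reversal).
#'
#' @param n_trials Number of trials per session.
#' @param reversal_trial 1-based index of the first reversal-phase trial; must
#'   lie in `(1, n_trials]`.
#' @param n_options Number of stimuli (2 or 3).
#' @param contingencies Numeric matrix (`n_options` x 2) of reward
#'   probabilities, rows named by role, columns `acquisition`/`reversal`.
#'   Defaults to 75:25 / 25:75 / 50:50 for 3 options and 70:30 / 30:70 for 2
#'   options (the predecessor two-choice design).
#' @param schedule_mode `"exact_ratio"` (fixed outcome multiset per phase,
#'   shuffled under a run-length constraint) or `"iid"` (independent draws).
#' @param max_run In `exact_ratio` mode, runs of `max_run` or more identical
#'   outcomes are forbidden for the two reversing roles; `Inf` disables the
#'   constraint. Ignored in `iid` mode.
#' @return A `task_config` object.
#' @export
task_config <- function(n_trials = 80L, reversal_trial = 41L, n_options = 3L,
                        contingencies = NULL,
                        schedule_mode = c("exact_ratio", "iid"),
                        max_run = 5L) {
  schedule_mode <- match.arg(schedule_mode)
  n_trials <- as.integer(n_trials)
  reversal_trial <- as.integer(reversal_trial)
  n_options <- as.integer(n_options)
  stopifnot(n_trials >= 2L, n_options %in% c(2L, 3L))
  if (reversal_trial <= 1L || reversal_trial > n_trials)
    stop("reversal_trial must lie in (1, n_trials]")
  if (is.null(contingencies)) {
    contingencies <- if (n_options == 3L)
      matrix(c(0.75, 0.25, 0.50, 0.25, 0.75, 0.50), ncol = 2,
             dimnames = list(c("RP", "PR", "NN"),
                             c("acquisition", "reversal")))
    else
      matrix(c(0.70, 0.30, 0.30, 0.70), ncol = 2,
             dimnames = list(c("RP", "PR"), c("acquisition", "reversal")))
  }
  contingencies <- as.matrix(contingencies)
  if (nrow(contingencies) != n_options || ncol(contingencies) != 2L)
    stop("contingencies must be an n_options x 2 matrix")
  if (any(contingencies < 0) || any(contingencies > 1))
    stop("reward probabilities must lie in [0, 1]")
  if (is.null(rownames(contingencies)))
    rownames(contingencies) <- c("RP", "PR", "NN")[seq_len(n_options)]
  colnames(contingencies) <- c("acquisition", "reversal")
  structure(
    list(n_trials = n_trials, reversal_trial = reversal_trial,
         n_options = n_options, contingencies = contingencies,
         schedule_mode = schedule_mode, max_run = max_run),
    class = "task_config")
}

#' @export
print.task_config <- function(x, ...) {
  cat(sprintf("<task_config> %d options, %d trials, reversal at trial %d, %s schedules\n",
              x$n_options, x$n_trials, x$reversal_trial, x$schedule_mode))
  print(x$contingencies)
  invisible(x)
}

#' Role names of a task configuration
#' @param config A [task_config()].
#' @return Character vector of role labels (e.g. `c("RP", "PR", "NN")`).
#' @export
task_roles <- function(config) rownames(config$contingencies)

#' Phase label of each trial
#' @param config A [task_config()].
#' @param trial Integer trial indices (1-based); defaults to all trials.
#' @return Character vector, `"acquisition"` or `"reversal"`.
#' @export
trial_phase <- function(config, trial = seq_len(config$n_trials)) {
  stopifnot(all(trial >= 1L), all(trial <= config$n_trials))
  ifelse(trial < config$reversal_trial, "acquisition", "reversal")
}

# cache of run-length-constrained arrangement counts, keyed by (nR, nP, max_run)
.arr_cache <- new.env(parent = emptyenv())

# DP table f[r+1, p+1, last, run]: number of valid completions given r rewards
# and p punishments remaining, previous symbol `last` (1 = reward,
# 2 = punishment) currently in a run of length `run`. Runs of length >= max_run
# are forbidden, so `run` ranges over 1..(max_run - 1).
arrangement_counts <- function(nR, nP, max_run) {
  key <- paste(nR, nP, max_run, sep = "_")
  if (!is.null(.arr_cache[[key]])) return(.arr_cache[[key]])
  mr <- max_run - 1L
  f <- array(0, dim = c(nR + 1L, nP + 1L, 2L, mr))
  f[1L, 1L, , ] <- 1
  for (tot in seq_len(nR + nP)) {
    for (r in max(0L, tot - nP):min(nR, tot)) {
      p <- tot - r
      for (last in 1:2) for (run in seq_len(mr)) {
        v <- 0
        if (r > 0) {
          if (last == 1L) {
            if (run < mr) v <- v + f[r, p + 1L, 1L, run + 1L]
          } else v <- v + f[r, p + 1L, 1L, 1L]
        }
        if (p > 0) {
          if (last == 2L) {
            if (run < mr) v <- v + f[r + 1L, p, 2L, run + 1L]
          } else v <- v + f[r + 1L, p, 2L, 1L]
        }
        f[r + 1L, p + 1L, last, run] <- v
      }
    }
  }
  .arr_cache[[key]] <- f
  f
}

# Draw a uniformly distributed arrangement of nR rewards (+1) and nP
# punishments (-1) with no run of >= max_run identical outcomes, by sequential
# sampling proportional to DP completion counts. Uses the current RNG stream.
sample_constrained_arrangement <- function(nR, nP, max_run) {
  if (!is.finite(max_run)) return(sample(rep(c(1, -1), c(nR, nP))))
  f <- arrangement_counts(nR, nP, max_run)
  mr <- max_run - 1L
  out <- numeric(nR + nP)
  r <- nR; p <- nP; last <- 0L; run <- 0L
  for (i in seq_len(nR + nP)) {
    wR <- if (r > 0 && !(last == 1L && run >= mr))
      f[r, p + 1L, 1L, if (last == 1L) run + 1L else 1L] else 0
    wP <- if (p > 0 && !(last == 2L && run >= mr))
      f[r + 1L, p, 2L, if (last == 2L) run + 1L else 1L] else 0
    if (wR + wP == 0)
      stop(sprintf("no arrangement of %d rewards / %d punishments satisfies max_run = %d",
                   nR, nP, max_run))
    if (stats::runif(1) < wR / (wR + wP)) {
      out[i] <- 1
      run <- if (last == 1L) run + 1L else 1L
      last <- 1L; r <- r - 1L
    } else {
      out[i] <- -1
      run <- if (last == 2L) run + 1L else 1L
      last <- 2L; p <- p - 1L
    }
  }
  out
}

#' Generate a feedback schedule
#'
#' Every stimulus role has a predetermined outcome (+1 reward, -1 punishment)
#' on every trial, so that identical seeds give identical, choice-independent
#' environments across agents. In `exact_ratio` mode the outcome counts per
#' role and phase hit `round(p * phase_length)` exactly and — for the two
#' reversing roles — the arrangement is drawn uniformly among arrangements
#' with no run of `max_run` or more identical outcomes. In `iid` mode each
#' entry is an independent Bernoulli draw.
#'
#' @param config A [task_config()].
#' @param seed Integer seed, or `NULL` to draw from the current RNG stream.
#' @param mode Override of `config$schedule_mode`.
#' @return A `feedback_schedule`: list with `outcomes` (`n_trials` x
#'   `n_options` matrix of ±1, columns named by role), `config`, `seed`,
#'   `mode`.
#' @export
generate_feedback_schedule <- function(config, seed = NULL, mode = NULL) {
  stopifnot(inherits(config, "task_config"))
  mode <- mode %||% config$schedule_mode
  mode <- match.arg(mode, c("exact_ratio", "iid"))
  roles <- task_roles(config)
  phase_len <- c(config$reversal_trial - 1L,
                 config$n_trials - config$reversal_trial + 1L)
  out <- with_seed(seed, {
    m <- matrix(0, config$n_trials, config$n_options,
                dimnames = list(NULL, roles))
    for (k in seq_along(roles)) {
      reversing <- config$contingencies[k, 1] != config$contingencies[k, 2]
      col <- numeric(0)
      for (ph in 1:2) {
        p <- config$contingencies[k, ph]
        len <- phase_len[ph]
        if (mode == "iid") {
          col <- c(col, ifelse(stats::runif(len) < p, 1, -1))
        } else {
          nR <- p * len
          if (abs(nR - round(nR)) > 1e-9)
            stop(sprintf(
              "exact_ratio mode requires an integer reward count; role %s phase %s gives %g rewards in %d trials",
              roles[k], colnames(config$contingencies)[ph], nR, len))
          nR <- as.integer(round(nR))
          mx <- if (reversing) config$max_run else Inf
          col <- c(col, sample_constrained_arrangement(nR, len - nR, mx))
        }
      }
      m[, k] <- col
    }
    m
  })
  structure(list(outcomes = out, config = config, seed = seed, mode = mode),
            class = "feedback_schedule")
}

#' @export
print.feedback_schedule <- function(x, ...) {
  cat(sprintf("<feedback_schedule> %d trials x %d roles (%s mode, seed %s)\n",
              nrow(x$outcomes), ncol(x$outcomes), x$mode,
              if (is.null(x$seed)) "stream" else x$seed))
  rew <- colSums(x$outcomes == 1)
  cat("rewards per role:", paste(colnames(x$outcomes), rew, collapse = ", "),
      "\n")
  invisible(x)
}

#' Assign stimulus roles from the first choice
#'
#' The first-chosen stimulus becomes role "RP" (mostly rewarded during
#' acquisition). Of the two remaining stimuli, "PR" is assigned uniformly at
#' random from the current RNG stream (the paradigm leaves the tie-break
#' open). With two stimuli the remaining one becomes "PR".
#'
#' @param first_choice The raw id of the first-chosen stimulus.
#' @param stimulus_ids Vector of distinct raw stimulus ids (length 2 or 3)
#'   including `first_choice`.
#' @return Named character vector mapping each raw id to its role.
#' @export
assign_roles <- function(first_choice, stimulus_ids) {
  stimulus_ids <- as.character(stimulus_ids)
  first_choice <- as.character(first_choice)
  if (anyDuplicated(stimulus_ids))
    stop("stimulus ids must be distinct")
  if (!length(stimulus_ids) %in% 2:3)
    stop("expected 2 or 3 stimulus ids")
  if (!first_choice %in% stimulus_ids)
    stop(sprintf("first choice '%s' is not among the stimulus ids", first_choice))
  rest <- setdiff(stimulus_ids, first_choice)
  roles <- setNames(rep(NA_character_, length(stimulus_ids)), stimulus_ids)
  roles[first_choice] <- "RP"
  if (length(rest) == 1L) {
    roles[rest] <- "PR"
  } else {
    pr <- rest[sample.int(2L, 1L)]
    roles[pr] <- "PR"
    roles[setdiff(rest, pr)] <- "NN"
  }
  roles
}

#' Look up the outcome a choice would receive
#'
#' Stateless lookup into a pre-generated [generate_feedback_schedule()].
#'
#' @param schedule A `feedback_schedule`.
#' @param trial 1-based trial index.
#' @param choice Role index (1-based column) or role name.
#' @return The scheduled outcome, -1 or +1.
#' @export
step_outcome <- function(schedule, trial, choice) {
  stopifnot(inherits(schedule, "feedback_schedule"))
  if (!(is.numeric(trial) && length(trial) == 1L && trial >= 1 &&
        trial <= nrow(schedule$outcomes)))
    stop("trial index out of range")
  if (is.character(choice)) {
    if (!choice %in% colnames(schedule$outcomes))
      stop(sprintf("unknown role '%s'", choice))
  } else if (!(choice >= 1 && choice <= ncol(schedule$outcomes))) {
    stop("choice index out of range")
  }
  schedule$outcomes[trial, choice]
}
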