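# Behavioural measures and statistics: RT-based trial filtering,
# chance-corrected accuracy, stay probabilities, the repeated-measures
# ANCOVA with continuous covariates, simple effects, and the drug-induced
# parameter-change statistics.

current_rewarded_role <- function(phase)
  ifelse(phase == "acquisition", "RP", "PR")

current_punished_role <- function(phase)
  ifelse(phase == "acquisition", "PR", "RP")

# chance-corrected accuracy columns; chance of selecting any one of the three
# stimuli is 1/3. pReward and pNeutral subtract 1/3 directly; avoidance is
# corrected as (1 - pPunish) - 2/3 so that chance-level behaviour scores 0 on
# every metric. pPunish - 1/3 is also reported for the complementary
# convention.
add_corrected_accuracy <- function(acc) {
  chance <- 1 / 3
  acc$pReward_corrected <- acc$pReward - chance
  acc$pAvoidPunish_corrected <- (1 - acc$pPunish) - (1 - chance)
  acc$pPunish_corrected <- acc$pPunish - chance
  acc$pNeutral_corrected <- acc$pNeutral - chance
  acc
}

check_trials_df <- function(trials, require_rt = FALSE) {
  need <- c("subject_id", "drug", "trial", "phase", "choice_role", "outcome")
  missing <- setdiff(need, names(trials))
  if (length(missing))
    stop("trial table lacks columns: ", paste(missing, collapse = ", "))
  if (require_rt && !"rt_ms" %in% names(trials))
    stop("trial table has no rt_ms column")
  invisible(trials)
}

#' Remove implausibly fast responses
#'
#' Drops trials with reaction time strictly faster than `threshold_ms`
#' (a response at exactly the threshold is kept); such responses are unlikely
#' to reflect a deliberate choice. The input is returned unchanged, with a
#' warning, when no reaction times are available.
#'
#' @param trials Trial table (columns `subject_id`, `drug`, `trial`, `phase`,
#'   `choice_role`, `outcome`, optionally `rt_ms`).
#' @param threshold_ms Exclusion threshold in milliseconds.
#' @return List with `trials` (filtered copy; the input is not modified) and
#'   `n_excluded`.
#' @export
filter_fast_rt <- function(trials, threshold_ms = 200) {
  check_trials_df(trials)
  if (!"rt_ms" %in% names(trials) || all(is.na(trials$rt_ms))) {
    warning("no reaction times available; returning trials unfiltered")
    return(list(trials = trials, n_excluded = 0L))
  }
  if (any(trials$rt_ms < 0, na.rm = TRUE))
    stop("negative reaction times")
  fast <- !is.na(trials$rt_ms) & trials$rt_ms < threshold_ms
  list(trials = trials[!fast, , drop = FALSE], n_excluded = sum(fast))
}

#' Chance-corrected accuracy per subject, session and phase
#'
#' For each phase the "rewarded" and "punished" roles are re-evaluated ("PR"
#' is the mostly-rewarded stimulus during reversal). Reported are the raw
#' selection probabilities and the chance-corrected scores: `pReward - 1/3`,
#' avoidance `(1 - pPunish) - 2/3`, and `pNeutral - 1/3`, so a uniform
#' random chooser scores 0 on every corrected metric.
#'
#' @param trials Trial table (see [filter_fast_rt()]).
#' @param config A [task_config()].
#' @return Data.frame with one row per subject x drug x phase; raw
#'   probabilities sum to 1 within a row.
#' @export
accuracy_metrics <- function(trials, config = task_config()) {
  check_trials_df(trials)
  if (any(!trials$phase %in% c("acquisition", "reversal")))
    stop("unknown phase labels")
  roles <- task_roles(config)
  if (any(!trials$choice_role %in% roles))
    stop("choice_role values outside the task's roles")
  key <- interaction(trials$subject_id, trials$drug, trials$phase,
                     drop = TRUE, sep = "\r")
  if (any(tabulate(key) == 0L)) stop("empty subject x drug x phase cell")
  sel <- vapply(roles, function(rl)
    tapply(trials$choice_role == rl, key, mean), numeric(nlevels(key)))
  parts <- do.call(rbind, strsplit(levels(key), "\r", fixed = TRUE))
  phase <- parts[, 3L]
  acc <- data.frame(
    subject_id = parts[, 1L], drug = parts[, 2L], phase = phase,
    pReward = sel[cbind(seq_len(nrow(parts)),
                        match(current_rewarded_role(phase), roles))],
    pPunish = sel[cbind(seq_len(nrow(parts)),
                        match(current_punished_role(phase), roles))],
    pNeutral = if ("NN" %in% roles) sel[, match("NN", roles)] else NA_real_,
    row.names = NULL)
  add_corrected_accuracy(acc[order(acc$subject_id, acc$drug, acc$phase), ])
}

#' Win-stay / lose-stay probabilities
#'
#' The probability of repeating the current trial's choice on the next trial,
#' conditioned on the current outcome (win = +1, loss = -1), per subject,
#' session and phase of the current trial. Chance level is 1/3 in the
#' 3-option task. Bins without any win (or loss) trials are reported as `NA`.
#'
#' @param trials Trial table.
#' @return Data.frame with columns `subject_id`, `drug`, `phase`,
#'   `p_stay_win`, `p_stay_loss`, `n_win`, `n_loss`.
#' @export
stay_probabilities <- function(trials) {
  check_trials_df(trials)
  ord <- order(trials$subject_id, trials$drug, trials$trial)
  trials <- trials[ord, ]
  out <- list()
  for (grp in split(trials,
                    interaction(trials$subject_id, trials$drug, drop = TRUE))) {
    if (nrow(grp) < 2L) stop("stay probabilities need at least 2 trials")
    cur <- grp[-nrow(grp), ]
    stay <- grp$choice_role[-1L] == cur$choice_role
    for (phase in unique(cur$phase)) {
      in_ph <- cur$phase == phase
      win <- in_ph & cur$outcome == 1
      loss <- in_ph & cur$outcome == -1
      out[[length(out) + 1L]] <- data.frame(
        subject_id = grp$subject_id[1L], drug = grp$drug[1L], phase = phase,
        p_stay_win = if (any(win)) mean(stay[win]) else NA_real_,
        p_stay_loss = if (any(loss)) mean(stay[loss]) else NA_real_,
        n_win = sum(win), n_loss = sum(loss))
    }
  }
  res <- do.call(rbind, out)
  res[order(res$subject_id, res$drug, res$phase), ]
}

# ---- repeated-measures ANCOVA machinery -----------------------------------
#
# All within-subject factors in this design have two levels, so every within
# effect reduces to a single subject-wise contrast score; regressing that
# score on the mean-centered covariates gives the exact univariate
# repeated-measures F tests (intercept -> the within effect itself,
# covariate slopes -> effect x covariate interactions), with
# df = (1, n - 1 - n_covariates). Huynh-Feldt epsilon is identically 1 for
# 2-level factors, so corrected and uncorrected p coincide.

# one contrast regression -> rows of the ANOVA report
contrast_rows <- function(score, covs, effect) {
  X <- cbind(`(Intercept)` = 1, as.matrix(covs))
  fit <- lm.fit(X, score)
  n <- length(score); pcol <- ncol(X)
  df2 <- n - pcol
  rss <- sum(fit$residuals^2)
  sigma2 <- rss / df2
  XtXinv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(diag(XtXinv) * sigma2)
  tval <- fit$coefficients / se
  Fval <- tval^2
  label <- if (effect == "(Intercept)") {
    c("(Intercept)", colnames(covs))  # covariate slopes = between-subject effects
  } else {
    c(effect, if (ncol(covs)) paste(effect, colnames(covs), sep = ":"))
  }
  data.frame(
    effect = label,
    F = unname(Fval), df1 = 1, df2 = df2,
    p = unname(2 * pt(abs(tval), df2, lower.tail = FALSE)),
    partial_eta2 = unname(Fval / (Fval + df2)),
    hf_epsilon = 1, p_hf = unname(2 * pt(abs(tval), df2, lower.tail = FALSE)),
    row.names = NULL)
}

# wide cell matrix (subjects x cells) + per-cell factor codes (+1/-1)
rm_anova_engine <- function(cells, codes, covs) {
  factors <- colnames(codes)
  effects <- unlist(lapply(seq_along(factors), function(k)
    combn(factors, k, paste, collapse = ":", simplify = FALSE)),
    recursive = FALSE)
  rows <- contrast_rows(rowMeans(cells), covs, "(Intercept)")
  for (eff in effects) {
    fs <- strsplit(eff, ":", fixed = TRUE)[[1L]]
    contrast <- apply(codes[, fs, drop = FALSE], 1, prod)
    score <- as.vector(cells %*% contrast) / ncol(cells)
    rows <- rbind(rows, contrast_rows(score, covs, eff))
  }
  structure(rows, class = c("anova_report", "data.frame"))
}

# accuracy table -> subjects x 8 cell matrix in Valence x Phase x Drug order,
# plus the cell code matrix
accuracy_cells <- function(accuracy) {
  need <- c("subject_id", "drug", "phase", "pReward_corrected",
            "pAvoidPunish_corrected")
  if (!all(need %in% names(accuracy)))
    stop("accuracy table lacks columns: ",
         paste(setdiff(need, names(accuracy)), collapse = ", "))
  long <- rbind(
    data.frame(subject_id = accuracy$subject_id, drug = accuracy$drug,
               phase = accuracy$phase, valence = "reward",
               value = accuracy$pReward_corrected),
    data.frame(subject_id = accuracy$subject_id, drug = accuracy$drug,
               phase = accuracy$phase, valence = "avoid",
               value = accuracy$pAvoidPunish_corrected))
  long$cell <- paste(long$valence, long$phase, long$drug, sep = ".")
  cell_levels <- as.vector(outer(
    c("reward", "avoid"),
    as.vector(outer(c("acquisition", "reversal"), c("placebo", "MPH"),
                    paste, sep = ".")), paste, sep = "."))
  subjects <- sort(unique(long$subject_id))
  cells <- matrix(NA_real_, length(subjects), length(cell_levels),
                  dimnames = list(subjects, cell_levels))
  idx <- cbind(match(long$subject_id, subjects),
               match(long$cell, cell_levels))
  if (anyNA(idx[, 2L])) stop("unexpected drug or phase labels")
  if (anyDuplicated(idx)) stop("duplicated subject x cell rows")
  cells[idx] <- long$value
  if (anyNA(cells)) {
    miss <- which(is.na(cells), arr.ind = TRUE)
    stop("incomplete within-subject design; missing cells e.g. ",
         paste(rownames(cells)[miss[1L, 1L]], cell_levels[miss[1L, 2L]],
               sep = " / "))
  }
  parts <- do.call(rbind, strsplit(cell_levels, ".", fixed = TRUE))
  codes <- cbind(Valence = ifelse(parts[, 1L] == "reward", 1, -1),
                 Phase = ifelse(parts[, 2L] == "acquisition", 1, -1),
                 Drug = ifelse(parts[, 3L] == "MPH", 1, -1))
  list(cells = cells, codes = codes, subjects = subjects)
}

center_covariates <- function(covariates, subjects) {
  if (is.null(covariates)) return(matrix(numeric(0), length(subjects), 0))
  stopifnot("subject_id" %in% names(covariates))
  m <- match(as.character(subjects), as.character(covariates$subject_id))
  if (anyNA(m)) stop("covariates missing for some subjects")
  covs <- covariates[m, setdiff(names(covariates), "subject_id"),
                     drop = FALSE]
  covs <- as.matrix(covs)
  if (!is.numeric(covs)) stop("covariates must be numeric")
  sweep(covs, 2, colMeans(covs))  # centered so within effects stay interpretable
}

#' Repeated-measures ANCOVA on chance-corrected accuracy
#'
#' The full factorial within-subject ANOVA with Valence (reward vs
#' punishment-avoidance), Phase (acquisition vs reversal) and Drug (MPH vs
#' placebo) as 2-level within-subject factors and the supplied subject
#' covariates (working-memory span, impulsivity) as mean-centered continuous
#' between-subject predictors. All main effects and interactions up to
#' Valence x Phase x Drug x covariate are reported with F, degrees of
#' freedom, p, partial eta squared, and the Huynh-Feldt epsilon (identically
#' 1 here, since 2-level factors cannot violate sphericity).
#'
#' @param accuracy Output of [accuracy_metrics()] (or the posterior-predictive
#'   equivalent): complete 2 phases x 2 drugs per subject.
#' @param covariates Optional data.frame with `subject_id` plus numeric
#'   covariate columns (e.g. `wm_span`, `bis`).
#' @return An `anova_report` data.frame.
#' @export
rm_anova <- function(accuracy, covariates = NULL) {
  ac <- accuracy_cells(accuracy)
  covs <- center_covariates(covariates, ac$subjects)
  rm_anova_engine(ac$cells, ac$codes, covs)
}

#' @export
print.anova_report <- function(x, ...) {
  y <- as.data.frame(x)
  for (col in intersect(c("F", "partial_eta2"), names(y)))
    y[[col]] <- round(y[[col]], 3)
  for (col in intersect(c("p", "p_hf"), names(y)))
    y[[col]] <- signif(y[[col]], 3)
  print.data.frame(y, ...)
  invisible(x)
}

#' Simple effects of a within-subject ANOVA
#'
#' Refits the omnibus model within each level of `split_by` (e.g. per Phase:
#' the Drug x covariate effects separately for acquisition and reversal),
#' which is how significant interactions are broken down for interpretation.
#'
#' @inheritParams rm_anova
#' @param split_by `"phase"`, `"valence"` or `"drug"`.
#' @return Named list of `anova_report`s, one per level.
#' @export
simple_effects <- function(accuracy, covariates = NULL,
                           split_by = c("phase", "valence", "drug")) {
  split_by <- match.arg(split_by)
  ac <- accuracy_cells(accuracy)
  covs <- center_covariates(covariates, ac$subjects)
  fac <- c(phase = "Phase", valence = "Valence", drug = "Drug")[[split_by]]
  lv <- list(Phase = c("acquisition", "reversal"),
             Valence = c("reward", "avoid"),
             Drug = c("placebo", "MPH"))[[fac]]
  code_for <- c(acquisition = 1, reversal = -1, reward = 1, avoid = -1,
                MPH = 1, placebo = -1)
  out <- lapply(lv, function(level) {
    keep <- ac$codes[, fac] == code_for[[level]]
    if (!any(keep) || all(keep)) stop("degenerate split: factor level missing")
    rm_anova_engine(ac$cells[, keep, drop = FALSE],
                    ac$codes[keep, setdiff(colnames(ac$codes), fac),
                             drop = FALSE],
                    covs)
  })
  setNames(out, lv)
}

#' Drug effects on fitted parameters
#'
#' The parameter-inference step for a drug-split model: a paired t-test of
#' the split parameter under MPH vs placebo, and Spearman correlations of the
#' per-subject drug-induced change with working-memory span, impulsivity,
#' and (optionally) the drug-induced change in raw performance (mean
#' chance-corrected accuracy across phases and valences, MPH minus placebo).
#'
#' @param param_table Output of [extract_subject_parameters()] for a split
#'   model, containing `<param>_placebo` and `<param>_mph` columns.
#' @param covariates Data.frame with `subject_id`, `wm_span`, `bis`.
#' @param accuracy Optional [accuracy_metrics()] table for the
#'   performance-change correlation.
#' @param param Name of the split parameter (default `"phi"`).
#' @return A `param_change_report` list: `t_test` (t, df, p, mean change),
#'   `spearman_wm`, `spearman_bis`, `spearman_performance` (each rho + p),
#'   and the per-subject `delta` values.
#' @export
parameter_change_stats <- function(param_table, covariates, accuracy = NULL,
                                   param = "phi") {
  cols <- paste0(param, c("_placebo", "_mph"))
  if (!all(cols %in% names(param_table)))
    stop(sprintf("param_table lacks %s columns", paste(cols, collapse = "/")))
  n <- nrow(param_table)
  if (n < 3L) stop("need at least 3 subjects")
  delta <- param_table[[cols[2L]]] - param_table[[cols[1L]]]
  tt <- if (sd(delta) == 0)
    list(statistic = c(t = 0), parameter = c(df = n - 1), p.value = 1)
  else t.test(param_table[[cols[2L]]], param_table[[cols[1L]]],
              paired = TRUE)
  m <- match(as.character(param_table$subject_id),
             as.character(covariates$subject_id))
  if (anyNA(m)) stop("covariates missing for some subjects")
  sp <- function(x, y) {
    ct <- suppressWarnings(cor.test(x, y, method = "spearman"))
    list(rho = unname(ct$estimate), p = ct$p.value)
  }
  perf <- NULL
  if (!is.null(accuracy)) {
    score <- (accuracy$pReward_corrected + accuracy$pAvoidPunish_corrected) / 2
    agg <- tapply(score, list(accuracy$subject_id, accuracy$drug), mean)
    dperf <- agg[match(as.character(param_table$subject_id),
                       rownames(agg)), "MPH"] -
      agg[match(as.character(param_table$subject_id), rownames(agg)),
          "placebo"]
    perf <- c(sp(delta, dperf), list(delta_performance = unname(dperf)))
  }
  structure(
    list(param = param,
         t_test = list(t = unname(tt$statistic), df = unname(tt$parameter),
                       p = tt$p.value, mean_delta = mean(delta)),
         spearman_wm = sp(delta, covariates$wm_span[m]),
         spearman_bis = sp(delta, covariates$bis[m]),
         spearman_performance = perf,
         delta = delta),
    class = "param_change_report")
}

#' @export
print.param_change_report <- function(x, ...) {
  cat(sprintf("<param_change_report> %s (MPH - placebo), n = %d\n", x$param,
              length(x$delta)))
  cat(sprintf("  paired t = %.2f, df = %d, p = %.3g (mean delta %.4f)\n",
              x$t_test$t, x$t_test$df, x$t_test$p, x$t_test$mean_delta))
  cat(sprintf("  Spearman vs WM span: rho = %.3f, p = %.3g\n",
              x$spearman_wm$rho, x$spearman_wm$p))
  cat(sprintf("  Spearman vs BIS:     rho = %.3f, p = %.3g\n",
              x$spearman_bis$rho, x$spearman_bis$p))
  if (!is.null(x$spearman_performance))
    cat(sprintf("  Spearman vs delta-performance: rho = %.3f, p = %.3g\n",
                x$spearman_performance$rho, x$spearman_performance$p))
  invisible(x)
}
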