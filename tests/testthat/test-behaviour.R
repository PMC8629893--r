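toy_trials <- function(choices, outcomes, rt = NULL, drug = "placebo",
                       subject = "s1") {
  n <- length(choices)
  cfg <- task_config()
  data.frame(subject_id = subject, session = 1L, drug = drug,
             trial = seq_len(n),
             phase = trial_phase(cfg, seq_len(n)),
             choice_role = choices, outcome = outcomes,
             rt_ms = if (is.null(rt)) NA_real_ else rt)
}

test_that("fast-RT filtering is strict and preserves the original", {
  tr <- toy_trials(c("RP", "PR", "NN", "RP"), c(1, -1, 1, 1),
                   rt = c(150, 250, 199, 300))
  out <- filter_fast_rt(tr)
  expect_equal(out$n_excluded, 2L)
  expect_equal(out$trials$trial, c(2L, 4L))
  expect_equal(nrow(tr), 4L)
  # exactly at threshold is kept ("faster than" is strict)
  at <- filter_fast_rt(toy_trials("RP", 1, rt = 200))
  expect_equal(at$n_excluded, 0L)
  all_slow <- filter_fast_rt(toy_trials(c("RP", "PR"), c(1, 1),
                                        rt = c(300, 900)))
  expect_equal(all_slow$n_excluded, 0L)
  expect_error(filter_fast_rt(toy_trials("RP", 1, rt = -4)), "negative")
  expect_warning(filter_fast_rt(toy_trials("RP", 1)), "no reaction times")
})

test_that("accuracy metrics match hand counts and the deterministic chooser", {
  # always choose RP: acquisition pReward_corrected = 2/3, reversal = -1/3
  tr <- toy_trials(rep("RP", 80), rep(1, 80))
  acc <- accuracy_metrics(tr)
  expect_equal(acc$pReward_corrected[acc$phase == "acquisition"], 2 / 3)
  expect_equal(acc$pReward_corrected[acc$phase == "reversal"], -1 / 3)
  expect_equal(acc$pAvoidPunish_corrected[acc$phase == "acquisition"], 1 / 3)
  expect_equal(acc$pReward + acc$pPunish + acc$pNeutral, rep(1, 2))

  # hand-computed 12-trial toy sequence (8 acquisition via short config)
  cfg <- task_config(n_trials = 12, reversal_trial = 9)
  ch <- c("RP", "NN", "RP", "PR", "RP", "RP", "NN", "RP",  # acq: 5 RP,2 NN,1 PR
          "PR", "PR", "RP", "NN")                          # rev: 2 PR,1 RP,1 NN
  tr2 <- data.frame(subject_id = "s1", session = 1L, drug = "placebo",
                    trial = 1:12, phase = trial_phase(cfg, 1:12),
                    choice_role = ch, outcome = rep(c(1, -1), 6))
  acc2 <- accuracy_metrics(tr2, cfg)
  acq <- acc2[acc2$phase == "acquisition", ]
  rev <- acc2[acc2$phase == "reversal", ]
  expect_equal(acq$pReward, 5 / 8); expect_equal(acq$pPunish, 1 / 8)
  expect_equal(rev$pReward, 2 / 4); expect_equal(rev$pPunish, 1 / 4)
  expect_equal(rev$pAvoidPunish_corrected, (1 - 1 / 4) - 2 / 3)

  # uniform random chooser: corrected metrics near 0 in expectation
  set.seed(15)
  big <- task_config(n_trials = 10000, reversal_trial = 5001)
  tr3 <- data.frame(subject_id = "s1", session = 1L, drug = "placebo",
                    trial = 1:10000, phase = trial_phase(big, 1:10000),
                    choice_role = sample(c("RP", "PR", "NN"), 10000, TRUE),
                    outcome = sample(c(-1, 1), 10000, TRUE))
  acc3 <- accuracy_metrics(tr3, big)
  expect_true(all(abs(acc3$pReward_corrected) < 0.02))
  expect_true(all(abs(acc3$pAvoidPunish_corrected) < 0.02))
  expect_true(all(abs(acc3$pNeutral_corrected) < 0.02))
})

test_that("stay probabilities capture perseveration, lose-shift and chance", {
  # perseverator: both probabilities 1
  tr <- toy_trials(rep("PR", 80), rep(c(1, -1), 40))
  st <- stay_probabilities(tr)
  expect_true(all(st$p_stay_win == 1))
  expect_true(all(st$p_stay_loss == 1))
  # strict lose-shift agent
  ch <- character(80); ch[1] <- "RP"
  out <- rep(c(-1, 1), 40)
  roles <- c("RP", "PR", "NN")
  for (t in 2:80)
    ch[t] <- if (out[t - 1] == -1)
      setdiff(roles, ch[t - 1])[1] else ch[t - 1]
  st2 <- stay_probabilities(toy_trials(ch, out))
  expect_true(all(st2$p_stay_loss == 0))
  expect_true(all(st2$p_stay_win == 1))
  # uniform random agent sits at the 1/3 chance level
  set.seed(16)
  big <- task_config(n_trials = 10000, reversal_trial = 5001)
  tr3 <- data.frame(subject_id = "s1", session = 1L, drug = "placebo",
                    trial = 1:10000, phase = trial_phase(big, 1:10000),
                    choice_role = sample(roles, 10000, TRUE),
                    outcome = sample(c(-1, 1), 10000, TRUE))
  st3 <- stay_probabilities(tr3)
  expect_true(all(abs(st3$p_stay_win - 1 / 3) < 0.03))
  expect_true(all(abs(st3$p_stay_loss - 1 / 3) < 0.03))
  # a bin with no losses is reported missing
  st4 <- stay_probabilities(toy_trials(c("RP", "RP", "NN"), c(1, 1, 1)))
  expect_true(is.na(st4$p_stay_loss[1]))
})

test_that("repeated-measures ANCOVA agrees with car::Anova and the paired t", {
  co <- generate_cohort(cohort_spec(n_subjects = 20), seed = 701)
  acc <- accuracy_metrics(co$trials)
  covs <- co$subjects[, c("subject_id", "wm_span", "bis")]
  mine <- rm_anova(acc, covs)
  expect_true(all(mine$F >= 0))
  expect_true(all(mine$p > 0 & mine$p <= 1))
  expect_true(all(mine$hf_epsilon == 1))
  expect_identical(mine$p, mine$p_hf)

  # independent implementation: multivariate repeated-measures ANOVA
  cells_order <- expand.grid(valence = c("reward", "avoid"),
                             phase = c("acquisition", "reversal"),
                             drug = c("placebo", "MPH"),
                             stringsAsFactors = FALSE)
  subj <- sort(unique(acc$subject_id))
  Y <- sapply(seq_len(nrow(cells_order)), function(i) {
    sel <- acc[acc$phase == cells_order$phase[i] &
                 acc$drug == cells_order$drug[i], ]
    sel <- sel[match(subj, sel$subject_id), ]
    if (cells_order$valence[i] == "reward") sel$pReward_corrected
    else sel$pAvoidPunish_corrected
  })
  wm <- covs$wm_span[match(subj, covs$subject_id)]
  bis <- covs$bis[match(subj, covs$subject_id)]
  wm <- wm - mean(wm); bis <- bis - mean(bis)
  idata <- data.frame(valence = factor(cells_order$valence),
                      phase = factor(cells_order$phase),
                      drug = factor(cells_order$drug))
  av <- car::Anova(lm(Y ~ wm + bis), idata = idata,
                   idesign = ~ valence * phase * drug, type = 3)
  uni <- summary(av, multivariate = FALSE)$univariate.tests
  pick <- function(eff) mine$F[mine$effect == eff]
  expect_equal(pick("(Intercept)"), unname(uni["(Intercept)", "F value"]),
               tolerance = 1e-6)
  expect_equal(pick("Valence"), unname(uni["valence", "F value"]),
               tolerance = 1e-6)
  expect_equal(pick("Phase:Drug"), unname(uni["phase:drug", "F value"]),
               tolerance = 1e-6)
  expect_equal(pick("Phase:Drug:wm_span"),
               unname(uni["wm:phase:drug", "F value"]), tolerance = 1e-6)
  expect_equal(pick("Valence:Phase:Drug:bis"),
               unname(uni["bis:valence:phase:drug", "F value"]),
               tolerance = 1e-6)

  # paired-t equivalence for a single 2-level within factor (no covariates)
  mine0 <- rm_anova(acc)
  dmat <- tapply(
    (acc$pReward_corrected + acc$pAvoidPunish_corrected) / 2,
    list(acc$subject_id, acc$drug), mean)
  tt <- t.test(dmat[, "MPH"], dmat[, "placebo"], paired = TRUE)
  expect_equal(mine0$F[mine0$effect == "Drug"],
               unname(tt$statistic)^2, tolerance = 1e-10)
})

test_that("incomplete designs and degenerate splits are rejected", {
  co <- generate_cohort(cohort_spec(n_subjects = 6), seed = 702)
  acc <- accuracy_metrics(co$trials)
  expect_error(rm_anova(acc[-1, ]), "missing cells")
  covs <- co$subjects[, c("subject_id", "wm_span", "bis")]
  se <- simple_effects(acc, covs, "phase")
  expect_named(se, c("acquisition", "reversal"))
  expect_true(all(c("Drug", "Drug:wm_span") %in% se$acquisition$effect))
  expect_false("Phase" %in% se$acquisition$effect)
  expect_error(rm_anova(acc, covs[-1, ]), "missing")
})

test_that("parameter-change statistics: degenerate and monotone cases, tie handling", {
  covs <- data.frame(subject_id = sprintf("s%02d", 1:20),
                     wm_span = 1:20, bis = rnorm(20))
  tab <- data.frame(subject_id = covs$subject_id,
                    phi_placebo = runif(20, 0.3, 0.7))
  # delta identically zero -> t = 0, p = 1
  tab$phi_mph <- tab$phi_placebo
  pc0 <- parameter_change_stats(tab, covs)
  expect_equal(pc0$t_test$t, 0)
  expect_equal(pc0$t_test$p, 1)
  # perfectly monotone delta vs WM -> Spearman rho = 1
  tab$phi_mph <- tab$phi_placebo + seq(0.01, 0.2, length.out = 20)
  pc1 <- parameter_change_stats(tab, covs)
  expect_equal(pc1$spearman_wm$rho, 1)
  # ties: matches the rank-then-Pearson oracle
  set.seed(17)
  for (i in 1:50) {
    x <- sample(1:6, 20, replace = TRUE)
    y <- sample(1:6, 20, replace = TRUE)
    ct <- suppressWarnings(cor.test(x, y, method = "spearman"))
    expect_equal(unname(ct$estimate), cor(rank(x), rank(y)),
                 tolerance = 1e-12)
  }
  expect_error(parameter_change_stats(tab[1:2, ], covs), "at least 3")
})
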