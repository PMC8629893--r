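test_that("EWA update matches hand-computed values exactly", {
  st <- new_learner_state(3)
  # n=1, V=0, rho=0, lambda=+1: n'=1, V'=1
  s1 <- ewa_update(st, 1, +1, phi = 0.5, rho = 0)
  expect_equal(s1$n[1], 1, tolerance = 1e-15)
  expect_equal(s1$V[1], 1, tolerance = 1e-15)
  # n=1, V=0, rho=1, phi=1, lambda=+1: n'=2, V'=0.5
  s2 <- ewa_update(st, 1, +1, phi = 1, rho = 1)
  expect_equal(s2$n[1], 2, tolerance = 1e-15)
  expect_equal(s2$V[1], 0.5, tolerance = 1e-15)
  # unchosen options untouched
  expect_equal(s2$V[2:3], c(0, 0))
  expect_equal(s2$n[2:3], c(1, 1))
  expect_error(ewa_update(st, 1, 0, 0.5, 0.5), "outcome")
  expect_error(ewa_update(st, 1, 1, 1.5, 0.5), "phi")
})

test_that("forgetting decays unchosen values toward the initial value", {
  st <- new_learner_state(3)
  st$V <- c(0.2, 0.8, -0.4)
  expect_equal(forget_unchosen(st, 1, 0)$V, st$V)
  expect_equal(forget_unchosen(st, 1, 1)$V, c(0.2, 0, 0))
  expect_equal(forget_unchosen(st, 1, 0.5)$V, c(0.2, 0.4, -0.2),
               tolerance = 1e-15)
  expect_error(forget_unchosen(st, 1, 1.2), "alpha_f")
})

test_that("hybrid update follows the associability recursion", {
  st <- new_learner_state(3)
  # single update from V=0, a=1, eta=0.5, lambda=+1 -> V=0.5
  s1 <- hybrid_update(st, 2, +1, eta = 0.5, kappa = 0.3)
  expect_equal(s1$V[2], 0.5, tolerance = 1e-15)
  expect_equal(s1$a[2], 0.7 * 1 + 0.3 * 1, tolerance = 1e-15)
  # zero prediction error: value unchanged, associability shrinks by (1-kappa)
  st2 <- new_learner_state(3); st2$V[1] <- 1
  s2 <- hybrid_update(st2, 1, +1, eta = 0.4, kappa = 0.25)
  expect_equal(s2$V[1], 1)
  expect_equal(s2$a[1], 0.75)
  # kappa = 0: associability constant (fixed-learning-rate delta rule)
  s3 <- hybrid_update(st, 3, -1, eta = 0.2, kappa = 0)
  expect_equal(s3$a[3], 1)
})

test_that("softmax is symmetric, uniform at beta 0, and matches hand values", {
  expect_equal(softmax_probs(c(2, 2, 2), 5), rep(1 / 3, 3))
  expect_equal(softmax_probs(c(3, -1, 0.5), 0), rep(1 / 3, 3))
  expect_equal(softmax_probs(c(1, 0, 0), log(2)), c(0.5, 0.25, 0.25),
               tolerance = 1e-15)
  expect_equal(sum(softmax_probs(c(500, -500, 0), 10)), 1)
  expect_error(softmax_probs(c(Inf, 0, 0), 1), "finite")
  expect_error(softmax_probs(c(1, 0, 0), -1), "beta")
})

test_that("model registry builds the full family with correct parameterisation", {
  expect_setequal(list_models(),
                  c("EWA", "EWA+F", "Hybrid", "Hybrid+F", "EWA+F+dphi",
                    "EWA+F+drho", "EWA+F+dalpha_f", "EWA+F+dbeta"))
  expect_equal(prl_model("EWA")$n_params, 3L)
  expect_equal(prl_model("Hybrid+F")$n_params, 4L)
  m <- prl_model("EWA+F+dphi")
  expect_equal(m$n_params, 5L)
  expect_equal(m$param_names,
               c("phi_placebo", "rho", "beta", "alpha_f", "phi_mph"))
  # transforms: sigmoid at 0 -> 0.5, exp at 0 -> 1; split routing by drug
  x <- c(0, 0, 0, 0, 2)
  expect_equal(unname(constrained_params(m, x, "placebo")),
               c(0.5, 0.5, 1, 0.5))
  expect_equal(unname(constrained_params(m, x, "MPH"))[1], plogis(2))
})

test_that("likelihood equals the independent brute-force oracle", {
  set.seed(11)
  for (name in c("EWA", "EWA+F", "Hybrid", "Hybrid+F", "EWA+F+dphi",
                 "EWA+F+dbeta")) {
    model <- prl_model(name)
    for (rep in 1:5) {
      sessions <- list(random_session(drug = "placebo"),
                       random_session(drug = "MPH"))
      x <- rnorm(model$n_params)
      expected <- oracle_nll(model$kind, sessions,
                             oracle_pars_by_drug(model, x))
      expect_equal(negative_log_likelihood(model, x, sessions), expected,
                   tolerance = 1e-12)
      expect_equal(negative_log_likelihood(model, x, sessions, engine = "r"),
                   expected, tolerance = 1e-12)
    }
  }
})

test_that("EWA+F with alpha_f = 0 reproduces EWA bit-comparably", {
  set.seed(3)
  ewa <- prl_model("EWA")
  ewaf <- prl_model("EWA+F")
  for (rep in 1:10) {
    s <- random_session()
    x <- rnorm(3)
    expect_equal(negative_log_likelihood(ewaf, c(x, -745), s),
                 negative_log_likelihood(ewa, x, s), tolerance = 1e-12)
  }
})

test_that("single uniform trial gives NLL ln 3; greedy self-scoring is near 0", {
  cfg <- task_config(n_trials = 2, reversal_trial = 2)
  s <- prl_session(c(1, 1), c(1, 1), config = cfg)
  one <- prl_session(1, 1, config = cfg)
  expect_equal(negative_log_likelihood(prl_model("EWA"), c(0, 0, 0), one),
               log(3), tolerance = 1e-12)
  # near-deterministic agent scored under its own model
  agent <- simulate_agent("EWA+F", c(phi = 0.9, rho = 0.5, beta = 60,
                                     alpha_f = 0.1), seed = 5)
  x <- c(logit(0.9), logit(0.5), log(60), logit(0.1))
  nll <- negative_log_likelihood(prl_model("EWA+F"), x, agent)
  expect_lt(nll / 80, log(3) / 4)  # far below chance per trial
})

test_that("effective learning speed decreases with experience under rho > 0", {
  st <- new_learner_state(3)
  increments <- numeric(10)
  for (t in 1:10) {
    old <- st$V[1]
    st <- ewa_update(st, 1, +1, phi = 1, rho = 1)
    increments[t] <- st$V[1] - old
  }
  expect_true(all(diff(increments) < 0))
})

test_that("likelihood is invariant to consistent relabelling of options", {
  set.seed(21)
  model <- prl_model("EWA+F")
  s <- random_session()
  x <- rnorm(4)
  perm <- c(3L, 1L, 2L)
  s2 <- prl_session(perm[s$choices], s$outcomes, drug = s$drug,
                    config = s$config, subject_id = s$subject_id)
  expect_equal(negative_log_likelihood(model, x, s),
               negative_log_likelihood(model, x, s2), tolerance = 1e-12)
})

test_that("compiled gradient matches numerical gradient of the R-engine likelihood", {
  set.seed(31)
  model <- prl_model("EWA+F")
  sessions <- list(random_session())
  x <- rnorm(4, sd = 0.5)
  cl <- revlearn3:::fit_closures(model, sessions, rep(0, 4), rep(10, 4))
  g_cpp <- cl$gradient(x)
  f_r <- function(z) negative_log_likelihood(model, z, sessions,
                                             engine = "r") +
    0.5 * sum(z^2 / 10 + log(2 * pi * 10))
  h <- 1e-5 * (1 + abs(x))
  g_num <- vapply(1:4, function(i) {
    e <- numeric(4); e[i] <- h[i]
    (f_r(x + e) - f_r(x - e)) / (2 * h[i])
  }, numeric(1))
  expect_equal(g_cpp, g_num, tolerance = 1e-5)
})

test_that("split models demand both drug sessions and sessions validate inputs", {
  m <- prl_model("EWA+F+dphi")
  s <- random_session(drug = "placebo")
  expect_error(negative_log_likelihood(m, rnorm(5), list(s)), "both")
  expect_error(prl_session(c(1, 2), c(0, 1)), "-1 or \\+1")
  expect_error(prl_session(c(0, 2), c(1, 1)), "out of range")
  expect_error(prl_session(c(1, 2), c(1, 1), rt_ms = c(-5, 300)), "positive")
})
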