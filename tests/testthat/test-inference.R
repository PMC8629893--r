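test_that("Laplace evidence is exact on a conjugate-Gaussian toy problem", {
  # y_i ~ N(theta, s2) with known s2, prior theta ~ N(0, v):
  # closed-form log marginal likelihood and posterior mode
  set.seed(8)
  y <- rnorm(12, mean = 1.3, sd = 0.7)
  s2 <- 0.49; v <- 10; n <- length(y)
  objective <- function(theta)
    0.5 * sum((y - theta[1])^2) / s2 + n / 2 * log(2 * pi * s2) +
    0.5 * theta[1]^2 / v + 0.5 * log(2 * pi * v)
  post_var <- 1 / (n / s2 + 1 / v)
  post_mode <- post_var * sum(y) / s2
  # marginal: y ~ N(0, s2 I + v 11')
  Sigma <- diag(s2, n) + v
  log_marg <- -0.5 * (n * log(2 * pi) + determinant(Sigma)$modulus[1] +
                        t(y) %*% solve(Sigma, y))[1]
  fit <- map_laplace(objective, d = 1, n_restarts = 3, seed = 2)
  expect_equal(fit$par[1], post_mode, tolerance = 1e-6)
  expect_equal(fit$log_evidence, log_marg, tolerance = 1e-8)
  expect_true(fit$converged)
  expect_equal(fit$value, min(fit$restart_values, na.rm = TRUE))
})

test_that("fit_map is deterministic given a seed and recovers known parameters", {
  m <- prl_model("EWA+F")
  cfg <- task_config(n_trials = 400, reversal_trial = 201)
  true <- c(phi = 0.75, rho = 0.6, beta = 8, alpha_f = 0.3)
  agents <- lapply(1:6, function(i)
    simulate_agent("EWA+F", true, cfg, seed = 100 + i))
  fits <- lapply(seq_along(agents), function(i)
    fit_map(m, agents[[i]], n_restarts = 3, seed = i))
  f2 <- fit_map(m, agents[[1]], n_restarts = 3, seed = 1)
  expect_identical(fits[[1]]$par, f2$par)
  expect_identical(fits[[1]]$log_evidence, f2$log_evidence)
  phi_hat <- vapply(fits, function(f) f$par_constrained[["phi"]], numeric(1))
  af_hat <- vapply(fits, function(f) f$par_constrained[["alpha_f"]],
                   numeric(1))
  expect_lt(abs(mean(phi_hat) - true[["phi"]]), 0.1)
  expect_lt(abs(mean(af_hat) - true[["alpha_f"]]), 0.15)
  # Hessians symmetric, evidence finite
  for (f in fits) {
    expect_equal(f$hessian, t(f$hessian))
    expect_true(is.finite(f$log_evidence))
  }
})

test_that("adding a spurious parameter lowers the Laplace evidence (Occam penalty)", {
  cfg <- task_config(n_trials = 320, reversal_trial = 161)
  ewa <- prl_model("EWA"); ewaf <- prl_model("EWA+F")
  set.seed(77)
  wins <- replicate(60, {
    agent <- simulate_agent("EWA", c(phi = 0.8, rho = 0.5, beta = 6), cfg)
    fit3 <- fit_map(ewa, agent, n_restarts = 2)
    fit4 <- fit_map(ewaf, agent, n_restarts = 2)
    fit3$log_evidence > fit4$log_evidence
  })
  expect_gte(mean(wins), 0.8)
})

test_that("exceedance probabilities: symmetry, exact Beta tail, protection", {
  expect_equal(exceedance_prob(c(3, 3), n_samples = 2e5, seed = 1),
               c(0.5, 0.5), tolerance = 0.01)
  # K = 2 closed-form oracle vs Monte Carlo
  xp_mc <- exceedance_prob(c(8, 2), n_samples = 5e5, seed = 2)
  xp_exact <- pbeta(0.5, 8, 2, lower.tail = FALSE)
  expect_equal(xp_mc[1], xp_exact, tolerance = 0.005)
  expect_equal(exceedance_prob(c(8, 2), method = "exact2")[1], xp_exact,
               tolerance = 1e-12)
  # BOR = 1 collapses pxp to 1/K regardless of xp
  expect_equal(protected_exceedance_prob(c(9, 1, 1), bor = 1,
                                         n_samples = 1e4, seed = 3),
               rep(1 / 3, 3))
  # pxp identity and permutation invariance (exact 2-model route)
  a <- c(6, 3)
  xp <- exceedance_prob(a, method = "exact2")
  pxp <- protected_exceedance_prob(a, bor = 0.2, method = "exact2")
  expect_equal(pxp, (1 - 0.2) * xp + 0.2 / 2, tolerance = 1e-12)
  expect_equal(sum(pxp), 1, tolerance = 1e-12)
  expect_equal(rev(exceedance_prob(rev(a), method = "exact2")), xp)
  expect_error(exceedance_prob(c(1, 0)), "positive")
  expect_error(exceedance_prob(c(1, NA)), "positive")
})

test_that("hbi: responsibilities normalise, symmetric evidences give chance pxp", {
  # symmetric-evidence check on the mixture machinery itself
  L <- matrix(-50, nrow = 10, ncol = 4)
  alpha <- rep(1, 4)
  r <- revlearn3:::responsibility_matrix(L, alpha)
  expect_equal(rowSums(r), rep(1, 10), tolerance = 1e-12)
  expect_true(all(abs(r - 0.25) < 1e-12))
  # full hbi on a small simulated cohort
  sc <- small_cohort_data(8, seed = 301)
  h <- hbi(list(prl_model("EWA"), prl_model("EWA+F")), sc$data,
           n_restarts = 2, max_iter = 6, n_xp_samples = 1e4, seed = 5)
  expect_equal(rowSums(h$responsibilities), rep(1, 8), tolerance = 1e-12)
  expect_equal(sum(h$frequencies), 1, tolerance = 1e-12)
  expect_equal(sum(h$pxp), 1, tolerance = 1e-6)
  expect_equal(h$pxp, (1 - h$bor) * h$xp + h$bor / 2, tolerance = 1e-6)
  expect_gte(h$bor, 0); expect_lte(h$bor, 1)
  # free-energy trace recorded and non-decreasing (small numerical slack)
  expect_gte(length(h$free_energy), 2)
  expect_true(all(diff(h$free_energy) > -1e-3))
})

test_that("hbi with a single model shrinks subjects toward the group mean", {
  sc <- small_cohort_data(10, seed = 401)
  m <- prl_model("EWA+F")
  h <- hbi(list(m), sc$data, n_restarts = 2, max_iter = 6, seed = 6)
  base_fits <- fit_subjects(m, sc$data, n_restarts = 2, seed = 7)
  mu <- h$group_mean[[1]]
  theta_h <- t(vapply(h$fits[[1]], `[[`, numeric(4), "par"))
  theta_0 <- t(vapply(base_fits, `[[`, numeric(4), "par"))
  # average absolute deviation from the group mean shrinks under the
  # hierarchical prior
  dev_h <- mean(abs(sweep(theta_h, 2, mu)))
  dev_0 <- mean(abs(sweep(theta_0, 2, mu)))
  expect_lt(dev_h, dev_0)
})

test_that("subject parameter extraction reports constrained values and IQR", {
  sc <- small_cohort_data(6, seed = 501)
  fits <- fit_subjects(prl_model("EWA+F"), sc$data, n_restarts = 2, seed = 8)
  tab <- extract_subject_parameters(fits)
  expect_equal(nrow(tab), 6)
  expect_true(all(tab$phi > 0 & tab$phi < 1))
  expect_true(all(tab$beta > 0))
  summ <- attr(tab, "summary")
  # order-statistics oracle for the median
  expect_equal(summ$median[summ$param == "phi"],
               sort(tab$phi)[c(3, 4)] |> mean())
  expect_true(all(summ$q25 <= summ$median & summ$median <= summ$q75))
})
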