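# Shared fixtures and independent oracles for the test suite. Everything is
# generated in code; no data files.

# Independently coded brute-force likelihood: a plain trial loop over the
# update equations, deliberately separate from the package's likelihood
# implementations. pars_by_drug holds c(p1, p2, beta, alpha_f) per drug label
# (p1/p2 = phi/rho for EWA, eta/kappa for the hybrid).
oracle_nll <- function(kind, sessions, pars_by_drug) {
  if (inherits(sessions, "prl_session")) sessions <- list(sessions)
  total <- 0
  for (s in sessions) {
    p <- pars_by_drug[[s$drug]]
    K <- s$config$n_options
    V <- rep(0, K); n <- rep(1, K); a <- rep(1, K)
    for (t in seq_along(s$choices)) {
      z <- p[3] * V
      c_t <- s$choices[t]; lam <- s$outcomes[t]
      # stable log softmax (unconstrained hybrid trajectories can make the
      # value range huge on adversarial random sessions)
      total <- total - (z[c_t] - max(z) - log(sum(exp(z - max(z)))))
      if (kind == "ewa") {
        nn <- n[c_t] * p[2] + 1
        V[c_t] <- (V[c_t] * p[1] * n[c_t] + lam) / nn
        n[c_t] <- nn
      } else {
        dd <- lam - V[c_t]
        V[c_t] <- V[c_t] + p[1] * a[c_t] * dd
        a[c_t] <- (1 - p[2]) * a[c_t] + p[2] * abs(dd)
      }
      V[-c_t] <- (1 - p[4]) * V[-c_t]
    }
  }
  total
}

# unconstrained parameter vector -> per-drug constrained 4-slot vectors,
# mirroring the documented model parameterisation (sigmoid everywhere except
# the exp-transformed beta in slot 3)
oracle_pars_by_drug <- function(model, x) {
  nb <- length(model$base_params)
  tr <- function(xb) {
    v <- c(plogis(xb[1]), plogis(xb[2]), exp(xb[3]),
           if (nb == 4L) plogis(xb[4]) else 0)
    v
  }
  xb_pla <- x[seq_len(nb)]
  xb_mph <- xb_pla
  if (!is.null(model$split_param)) xb_mph[model$split_index] <- x[nb + 1L]
  list(placebo = tr(xb_pla), MPH = tr(xb_mph))
}

# a session with arbitrary (non-model-generated) choices and outcomes
random_session <- function(config = task_config(), drug = "placebo",
                           subject_id = "s1") {
  n <- config$n_trials
  prl_session(sample.int(config$n_options, n, replace = TRUE),
              sample(c(-1, 1), n, replace = TRUE), drug = drug,
              config = config, subject_id = subject_id)
}

# a small fitted-ready dataset: n subjects x 2 sessions simulated from EWA+F
small_cohort_data <- function(n_subjects, seed, b = 0, noise_sd = 0) {
  co <- generate_cohort(cohort_spec(n_subjects = n_subjects, b = b,
                                    noise_sd = noise_sd), seed = seed)
  list(cohort = co, data = sessions_from_trials(co$trials))
}
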