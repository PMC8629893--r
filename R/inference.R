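# Subject-level MAP estimation with Laplace evidence, hierarchical Bayesian
# model comparison across subjects, and random-effects model-selection
# statistics (model frequency, exceedance and protected exceedance
# probabilities, Bayes omnibus risk).

# central-difference Hessian with relative step h
num_hessian <- function(f, x, h = 1e-4) {
  d <- length(x)
  H <- matrix(0, d, d)
  hs <- h * (1 + abs(x))
  f0 <- f(x)
  for (i in seq_len(d)) {
    ei <- numeric(d); ei[i] <- hs[i]
    H[i, i] <- (f(x + ei) - 2 * f0 + f(x - ei)) / hs[i]^2
    if (i > 1) for (j in seq_len(i - 1)) {
      ej <- numeric(d); ej[j] <- hs[j]
      H[i, j] <- H[j, i] <-
        (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) + f(x - ei - ej)) /
        (4 * hs[i] * hs[j])
    }
  }
  H
}

# Cholesky of H, adding an escalating ridge if H is not positive definite.
# Returns list(chol, ridge).
chol_ridged <- function(H) {
  ridge <- 0
  scale <- mean(abs(diag(H))) + 1e-12
  for (k in 0:12) {
    R <- tryCatch(chol(H + diag(ridge, nrow(H))), error = function(e) NULL)
    if (!is.null(R)) return(list(chol = R, ridge = ridge))
    ridge <- if (ridge == 0) 1e-8 * scale else ridge * 10
  }
  stop("Hessian could not be regularized to positive definite")
}

#' Multi-start MAP optimisation with Laplace-approximated evidence
#'
#' Minimises an arbitrary negative log posterior `objective` over `d`
#' unconstrained parameters by multi-start BFGS, computes the Hessian at the
#' best optimum by central finite differences, and returns the Laplace
#' approximation to the log marginal likelihood,
#' `-objective + (d/2) log(2 pi) - log det(H) / 2`.
#'
#' @param objective Function of a length-`d` numeric vector returning the
#'   negative log posterior (negative log likelihood plus negative log
#'   prior).
#' @param d Number of parameters.
#' @param gradient Optional gradient function; finite differences otherwise.
#' @param n_restarts Number of optimisation starts (>= 1). The first start is
#'   `init_mean` (or the supplied `init`); the rest are drawn from
#'   N(`init_mean`, `init_sd^2`).
#' @param seed Optional seed for the restart draws.
#' @param init Optional explicit first start.
#' @param init_mean,init_sd Location and spread of the random starts
#'   (defaults: the prior scale, mean 0 and sd `sqrt(10)`).
#' @return A `map_fit` list: `par`, `value` (best objective), `hessian`,
#'   `log_evidence`, `grad_norm`, `ridge` (0 unless the Hessian needed
#'   regularisation), `n_restarts`, `restart_values`, `converged`.
#' @export
map_laplace <- function(objective, d, gradient = NULL, n_restarts = 5L,
                        seed = NULL, init = NULL,
                        init_mean = rep(0, d), init_sd = rep(sqrt(10), d)) {
  stopifnot(n_restarts >= 1L)
  with_seed(seed, {
    starts <- matrix(rnorm(n_restarts * d, mean = init_mean, sd = init_sd),
                     nrow = n_restarts, byrow = TRUE)
    starts[1L, ] <- if (is.null(init)) init_mean else init
    best <- NULL
    vals <- rep(NA_real_, n_restarts)
    conv <- logical(n_restarts)
    for (r in seq_len(n_restarts)) {
      fit <- tryCatch(
        optim(starts[r, ], objective, gr = gradient, method = "BFGS",
              control = list(maxit = 500, reltol = 1e-12)),
        error = function(e) NULL)
      if (is.null(fit)) next
      vals[r] <- fit$value
      conv[r] <- fit$convergence == 0
      if (is.null(best) || fit$value < best$value) best <- fit
    }
    if (is.null(best))
      stop("all optimisation restarts failed; check the objective and data")
    H <- num_hessian(objective, best$par)
    H <- (H + t(H)) / 2
    cr <- chol_ridged(H)
    log_det <- 2 * sum(log(diag(cr$chol)))
    g <- if (is.null(gradient)) {
      hs <- 1e-6 * (1 + abs(best$par))
      vapply(seq_len(d), function(i) {
        e <- numeric(d); e[i] <- hs[i]
        (objective(best$par + e) - objective(best$par - e)) / (2 * hs[i])
      }, numeric(1))
    } else gradient(best$par)
    structure(
      list(par = best$par, value = best$value,
           hessian = H + diag(cr$ridge, d),
           log_evidence = -best$value + d / 2 * log(2 * pi) - log_det / 2,
           grad_norm = sqrt(sum(g^2)), ridge = cr$ridge,
           n_restarts = n_restarts, restart_values = vals,
           converged = any(conv)),
      class = "map_fit")
  })
}

# compiled objective/gradient closures for one subject under one model
fit_closures <- function(model, sessions, prior_mean, prior_var) {
  choices <- lapply(sessions, `[[`, "choices")
  outcomes <- lapply(sessions, `[[`, "outcomes")
  drug <- vapply(sessions, function(s) as.integer(s$drug == "MPH"),
                 integer(1))
  n_options <- sessions[[1L]]$config$n_options
  base_n <- length(model$base_params)
  split0 <- if (is.null(model$split_param)) -1L else model$split_index - 1L
  list(
    objective = function(x)
      map_objective_cpp(x, choices, outcomes, drug, model$model_code, base_n,
                        split0, prior_mean, prior_var, n_options),
    gradient = function(x)
      map_gradient_cpp(x, choices, outcomes, drug, model$model_code, base_n,
                       split0, prior_mean, prior_var, n_options))
}

#' Fit one subject by MAP with a Gaussian prior
#'
#' Minimises the negative log likelihood plus the negative log of independent
#' Gaussian priors on the unconstrained scale (default N(0, 10) for every
#' parameter) and Laplace-approximates the subject's log model evidence.
#'
#' @param model A [prl_model()].
#' @param sessions A `prl_session` or list of them (one subject; split models
#'   need both drug labels).
#' @param n_restarts Optimisation restarts.
#' @param seed Optional seed for restart draws.
#' @param prior_mean,prior_var Prior mean/variance vectors on the
#'   unconstrained scale (recycled to `model$n_params`).
#' @param init Optional warm start.
#' @return A `subject_fit`: the `map_fit` fields plus `model`, `subject_id`,
#'   `par_constrained` (named per-session-independent values; split
#'   parameters reported for both sessions).
#' @export
fit_map <- function(model, sessions, n_restarts = 5L, seed = NULL,
                    prior_mean = NULL, prior_var = NULL, init = NULL) {
  sessions <- check_sessions(model, sessions)
  d <- model$n_params
  prior_mean <- rep_len(prior_mean %||% 0, d)
  prior_var <- rep_len(prior_var %||% 10, d)
  cl <- fit_closures(model, sessions, prior_mean, prior_var)
  fit <- map_laplace(cl$objective, d, gradient = cl$gradient,
                     n_restarts = n_restarts, seed = seed, init = init,
                     init_mean = prior_mean, init_sd = sqrt(prior_var))
  fit$model <- model$name
  fit$subject_id <- sessions[[1L]]$subject_id
  pc <- vapply(seq_len(d), function(i)
    model$params[[i]]$transform(fit$par[i]), numeric(1))
  fit$par_constrained <- setNames(pc, model$param_names)
  class(fit) <- c("subject_fit", "map_fit")
  fit
}

#' @export
print.subject_fit <- function(x, ...) {
  cat(sprintf("<subject_fit> %s, subject %s: objective %.3f, log evidence %.3f\n",
              x$model, x$subject_id, x$value, x$log_evidence))
  print(round(x$par_constrained, 4))
  invisible(x)
}

#' Fit every subject of a dataset non-hierarchically
#'
#' @param model A [prl_model()].
#' @param data List of subjects, each a list of `prl_session`s.
#' @param n_restarts,seed,prior_mean,prior_var Passed to [fit_map()]; the
#'   seed makes the whole sweep reproducible.
#' @return List of `subject_fit` objects.
#' @export
fit_subjects <- function(model, data, n_restarts = 5L, seed = NULL,
                         prior_mean = NULL, prior_var = NULL) {
  with_seed(seed, lapply(data, function(sess)
    fit_map(model, sess, n_restarts = n_restarts, prior_mean = prior_mean,
            prior_var = prior_var)))
}

# variational free energy of the Dirichlet mixture over model labels, given
# the subject-by-model log evidence matrix L, responsibilities r and the
# Dirichlet posterior alpha / prior alpha0
mixture_elbo <- function(L, r, alpha, alpha0) {
  eln <- digamma(alpha) - digamma(sum(alpha))
  lnB <- function(a) sum(lgamma(a)) - lgamma(sum(a))
  sum(r * L) + sum(sweep(r, 2, eln, `*`)) - sum(r * log(pmax(r, 1e-300))) +
    (lnB(alpha) - lnB(alpha0)) + sum((alpha0 - alpha) * eln)
}

# responsibilities: rows of softmax(L + E[ln pi])
responsibility_matrix <- function(L, alpha) {
  eln <- digamma(alpha) - digamma(sum(alpha))
  z <- sweep(L, 2, eln, `+`)
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Exceedance probability of a Dirichlet model posterior
#'
#' The probability, under `Dirichlet(alpha)`, that each model's population
#' frequency exceeds all others'. Estimated by seeded Monte-Carlo sampling;
#' for two models an exact Beta tail integral is available.
#'
#' @param alpha Positive Dirichlet concentration vector.
#' @param n_samples Monte-Carlo draws.
#' @param seed Optional seed.
#' @param method `"mc"` or `"exact2"` (two models only).
#' @return Probability vector summing to 1.
#' @export
exceedance_prob <- function(alpha, n_samples = 1e6, seed = NULL,
                            method = c("mc", "exact2")) {
  method <- match.arg(method)
  if (any(!is.finite(alpha)) || any(alpha <= 0))
    stop("alpha must be positive and finite")
  K <- length(alpha)
  if (method == "exact2") {
    stopifnot(K == 2L)
    p1 <- stats::pbeta(0.5, alpha[1], alpha[2], lower.tail = FALSE)
    return(c(p1, 1 - p1))
  }
  with_seed(seed, {
    wins <- numeric(K)
    left <- n_samples
    while (left > 0) {
      n <- min(left, 1e5)
      g <- matrix(rgamma(n * K, shape = rep(alpha, each = n)), nrow = n)
      wins <- wins + tabulate(max.col(g), nbins = K)
      left <- left - n
    }
    wins / n_samples
  })
}

#' Protected exceedance probability
#'
#' Shrinks exceedance probabilities toward chance by the Bayes omnibus risk
#' (BOR), the posterior probability that all models are equally frequent:
#' `pxp = (1 - bor) * xp + bor / K`.
#'
#' @param alpha Positive Dirichlet concentration vector.
#' @param bor Bayes omnibus risk in `[0, 1]`.
#' @param n_samples,seed,method Passed to [exceedance_prob()].
#' @return Probability vector summing to 1.
#' @export
protected_exceedance_prob <- function(alpha, bor, n_samples = 1e6,
                                      seed = NULL, method = c("mc", "exact2")) {
  stopifnot(length(bor) == 1L, is.finite(bor), bor >= 0, bor <= 1)
  xp <- exceedance_prob(alpha, n_samples, seed, method)
  (1 - bor) * xp + bor / length(alpha)
}

#' Hierarchical Bayesian inference across subjects and models
#'
#' Random-effects scheme in the style of hierarchical Bayesian model
#' comparison toolboxes: each subject's parameters are Laplace-fitted under a
#' model-specific group Gaussian prior; an EM loop alternates (i) posterior
#' responsibilities of subjects over models under a Dirichlet prior on model
#' frequencies with (ii) re-estimation of the group means/variances from
#' responsibility-weighted subject posteriors and re-fitting of the subjects
#' under the updated priors. Model-level statistics (frequencies, exceedance
#' and protected exceedance probabilities, Bayes omnibus risk) are computed
#' from the final evidence matrix. The free-energy trace of the mixture is
#' recorded; convergence is declared when successive free energies differ by
#' less than `tol`.
#'
#' @param models List of [prl_model()]s (>= 2 for model comparison; a single
#'   model gives empirical-Bayes shrinkage of its parameters).
#' @param data List of subjects, each a list of `prl_session`s.
#' @param n_restarts Restarts for the initial subject fits.
#' @param max_iter,tol EM iteration cap and per-subject free-energy
#'   tolerance: convergence is declared when successive free energies differ
#'   by less than `tol * N`.
#' @param alpha0 Dirichlet prior concentration per model.
#' @param prior_mean,prior_var Initial (top-level) prior on the unconstrained
#'   scale.
#' @param var_floor Lower bound on group variances.
#' @param n_xp_samples Monte-Carlo draws for the exceedance probabilities.
#' @param seed Seed for the whole procedure.
#' @return An `hbi_result` with `model_names`, `alpha`, `frequencies`,
#'   `responsibilities`, `xp`, `bor`, `pxp`, `group_mean`/`group_var` (per
#'   model, unconstrained), `fits` (per model, per subject), `evidence`
#'   matrix, `free_energy` trace, `converged`, `n_iter`.
#' @export
hbi <- function(models, data, n_restarts = 5L, max_iter = 20L, tol = 0.01,
                alpha0 = 1, prior_mean = 0, prior_var = 10,
                var_floor = 1e-3, n_xp_samples = 1e6, seed = NULL) {
  if (inherits(models, "prl_model")) models <- list(models)
  stopifnot(length(data) >= 2L, length(models) >= 1L)
  K <- length(models); N <- length(data)
  model_names <- vapply(models, `[[`, character(1), "name")
  with_seed(seed, {
    fits <- lapply(models, function(m)
      lapply(data, function(sess)
        fit_map(m, sess, n_restarts = n_restarts, prior_mean = prior_mean,
                prior_var = prior_var)))
    group_mean <- lapply(models, function(m) rep(prior_mean, m$n_params))
    group_var <- lapply(models, function(m) rep(prior_var, m$n_params))
    evidence <- function() vapply(fits, function(fm)
      vapply(fm, `[[`, numeric(1), "log_evidence"), numeric(N))
    L <- evidence()
    alpha0v <- rep(alpha0, K)
    alpha <- alpha0v
    trace <- numeric(0)
    converged <- FALSE
    iter <- 0L
    repeat {
      iter <- iter + 1L
      r <- responsibility_matrix(L, alpha)
      alpha <- alpha0v + colSums(r)
      fe <- mixture_elbo(L, r, alpha, alpha0v)
      trace <- c(trace, fe)
      if (iter > 1L && abs(fe - trace[iter - 1L]) < tol * N) {
        converged <- TRUE
        break
      }
      if (iter >= max_iter) break
      for (m in seq_len(K)) {
        d <- models[[m]]$n_params
        w <- r[, m] + 1e-8
        sw <- sum(w)
        theta <- t(vapply(fits[[m]], `[[`, numeric(d), "par"))
        if (d == 1L) theta <- matrix(theta, ncol = 1L)
        mu <- colSums(w * theta) / sw
        s2 <- t(vapply(fits[[m]], function(f)
          diag(chol2inv(chol(f$hessian)))[seq_len(d)], numeric(d)))
        if (d == 1L) s2 <- matrix(s2, ncol = 1L)
        v <- colSums(w * (sweep(theta, 2, mu)^2 + s2)) / sw
        group_mean[[m]] <- mu
        group_var[[m]] <- pmax(v, var_floor)
        fits[[m]] <- lapply(seq_len(N), function(n)
          fit_map(models[[m]], data[[n]], n_restarts = 1L,
                  prior_mean = mu, prior_var = group_var[[m]],
                  init = fits[[m]][[n]]$par))
      }
      L <- evidence()
    }
    r <- responsibility_matrix(L, alpha)
    freq <- alpha / sum(alpha)
    xp <- if (K == 1L) 1 else exceedance_prob(alpha, n_xp_samples)
    f0 <- sum(apply(L, 1, function(l) {
      m <- max(l); m + log(sum(exp(l - m)))
    })) - N * log(K)
    f1 <- trace[length(trace)]
    bor <- if (K == 1L) 0 else 1 / (1 + exp(f1 - f0))
    pxp <- (1 - bor) * xp + bor / K
    structure(
      list(model_names = model_names, alpha = alpha, frequencies = freq,
           responsibilities = r, xp = xp, bor = bor, pxp = pxp,
           group_mean = setNames(group_mean, model_names),
           group_var = setNames(group_var, model_names),
           fits = setNames(fits, model_names), evidence = L,
           free_energy = trace, converged = converged, n_iter = iter),
      class = "hbi_result")
  })
}

#' @export
print.hbi_result <- function(x, ...) {
  cat(sprintf("<hbi_result> %d models, %d subjects, %d iterations (%s), BOR %.3f\n",
              length(x$model_names), nrow(x$responsibilities), x$n_iter,
              if (x$converged) "converged" else "not converged", x$bor))
  print(data.frame(model = x$model_names,
                   frequency = round(x$frequencies, 3),
                   xp = round(x$xp, 3), pxp = round(x$pxp, 3)))
  invisible(x)
}

#' Per-subject parameter table on the constrained scale
#'
#' Collects the non-hierarchical MAP estimates (the first estimation step) on
#' the constrained scale — the values used for all downstream parameter
#' statistics, avoiding shrinkage-induced bias from the hierarchical step —
#' and summarises each parameter by its median and 25-75% range.
#'
#' @param fits List of `subject_fit`s for one model (e.g. [fit_subjects()]).
#' @return A data.frame with one row per subject; attribute `"summary"` holds
#'   per-parameter `median`, `q25`, `q75`.
#' @export
extract_subject_parameters <- function(fits) {
  stopifnot(length(fits) >= 1L,
            all(vapply(fits, inherits, logical(1), "subject_fit")))
  if (!all(vapply(fits, `[[`, logical(1), "converged")))
    warning("some fits did not report optimiser convergence")
  tab <- as.data.frame(t(vapply(fits, `[[`,
                                numeric(length(fits[[1L]]$par_constrained)),
                                "par_constrained")))
  tab <- cbind(subject_id = vapply(fits, function(f)
    as.character(f$subject_id), character(1)), tab)
  rownames(tab) <- NULL
  pars <- setdiff(names(tab), "subject_id")
  summ <- data.frame(
    param = pars,
    median = vapply(pars, function(p) median(tab[[p]]), numeric(1)),
    q25 = vapply(pars, function(p)
      unname(quantile(tab[[p]], 0.25)), numeric(1)),
    q75 = vapply(pars, function(p)
      unname(quantile(tab[[p]], 0.75)), numeric(1)),
    row.names = NULL)
  attr(tab, "summary") <- summ
  tab
}
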