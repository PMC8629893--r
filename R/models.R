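#' Logistic and logit transforms
#'
#' The logistic (sigmoid) maps the real line onto (0, 1) and is used to
#' constrain unit-interval parameters; `logit` is its inverse.
#' @param x,p Numeric vectors.
#' @return Numeric vector.
#' @export
sigmoid <- function(x) ifelse(x >= 0, 1 / (1 + exp(-x)), exp(x) / (1 + exp(x)))

#' @rdname sigmoid
#' @export
logit <- function(p) {
  stopifnot(all(p > 0 & p < 1))
  log(p / (1 - p))
}

#' Parameter specification
#'
#' A model parameter with its theoretical constraint, the monotone transform
#' from the unconstrained fitting scale to the constrained scale (logistic for
#' unit-interval parameters, exponential for positive ones), and a weakly
#' informative Gaussian prior N(0, 10) on the unconstrained scale.
#'
#' @param name Parameter name.
#' @param constraint `"unit_interval"` or `"positive"`.
#' @param prior_mean,prior_var Prior mean and variance on the unconstrained
#'   scale.
#' @return A `param_spec` object with elements `transform` and
#'   `inverse_transform`.
#' @export
param_spec <- function(name, constraint = c("unit_interval", "positive"),
                       prior_mean = 0, prior_var = 10) {
  constraint <- match.arg(constraint)
  stopifnot(prior_var > 0)
  transform <- if (constraint == "unit_interval") sigmoid else exp
  inverse <- if (constraint == "unit_interval") logit else log
  structure(list(name = name, constraint = constraint, transform = transform,
                 inverse_transform = inverse, prior_mean = prior_mean,
                 prior_var = prior_var),
            class = "param_spec")
}

.model_names <- c("EWA", "EWA+F", "Hybrid", "Hybrid+F",
                  "EWA+F+dphi", "EWA+F+drho", "EWA+F+dalpha_f", "EWA+F+dbeta")

#' The model registry
#'
#' Constructs a model of the 2 x 2 base family (EWA or Pearce-Hall hybrid,
#' with or without forgetting of unchosen values) or one of the four
#' drug-split extensions of EWA+F in which a single parameter is estimated
#' separately for placebo and methylphenidate sessions.
#'
#' Base parameters (in order): EWA family `phi` (inverse learning rate,
#' unit interval), `rho` (experience decay, unit interval), `beta` (inverse
#' temperature, positive); hybrid family `eta` (learning rate), `kappa`
#' (associability update rate), `beta`. The `+F` variants append `alpha_f`
#' (forgetting rate, unit interval). Split models append a second copy of the
#' split parameter used on methylphenidate sessions; the base slot then holds
#' the placebo value.
#'
#' @param name One of `"EWA"`, `"EWA+F"`, `"Hybrid"`, `"Hybrid+F"`,
#'   `"EWA+F+dphi"`, `"EWA+F+drho"`, `"EWA+F+dalpha_f"`, `"EWA+F+dbeta"`.
#' @return A `prl_model` object.
#' @export
prl_model <- function(name) {
  name <- match.arg(name, .model_names)
  kind <- if (startsWith(name, "EWA")) "ewa" else "hybrid"
  has_f <- grepl("\\+F", name)
  split <- if (grepl("\\+d", name)) sub(".*\\+d", "", name) else NULL
  base <- if (kind == "ewa") c("phi", "rho", "beta") else
    c("eta", "kappa", "beta")
  if (has_f) base <- c(base, "alpha_f")
  constraint <- ifelse(base == "beta", "positive", "unit_interval")
  par_names <- base
  if (!is.null(split)) {
    stopifnot(split %in% base)
    par_names[base == split] <- paste0(split, "_placebo")
    par_names <- c(par_names, paste0(split, "_mph"))
    constraint <- c(constraint, constraint[base == split])
  }
  params <- Map(param_spec, par_names, constraint)
  structure(
    list(name = name, kind = kind, has_forgetting = has_f,
         base_params = base, split_param = split,
         split_index = if (is.null(split)) NA_integer_ else match(split, base),
         params = params, param_names = par_names,
         n_params = length(par_names),
         model_code = if (kind == "ewa") 1L else 2L),
    class = "prl_model")
}

#' @export
print.prl_model <- function(x, ...) {
  cat(sprintf("<prl_model> %s: %s family%s, parameters %s\n", x$name,
              if (x$kind == "ewa") "EWA" else "Pearce-Hall hybrid",
              if (x$has_forgetting) " with forgetting" else "",
              paste(x$param_names, collapse = ", ")))
  if (!is.null(x$split_param))
    cat(sprintf("  '%s' estimated separately per drug session\n",
                x$split_param))
  invisible(x)
}

#' Names of all available models
#' @return Character vector of registry names.
#' @export
list_models <- function() .model_names

#' Map unconstrained parameters to the constrained scale
#'
#' @param model A [prl_model()].
#' @param x Numeric vector on the unconstrained scale, length
#'   `model$n_params`.
#' @param drug For split models, which session's parameter set to return
#'   (`"placebo"` or `"MPH"`).
#' @return Named numeric vector of the model's base parameters on their
#'   constrained scales (`alpha_f` = 0 for models without forgetting).
#' @export
constrained_params <- function(model, x, drug = "placebo") {
  stopifnot(inherits(model, "prl_model"), length(x) == model$n_params)
  nb <- length(model$base_params)
  xb <- x[seq_len(nb)]
  if (!is.null(model$split_param) && drug == "MPH")
    xb[model$split_index] <- x[nb + 1L]
  vals <- vapply(seq_len(nb), function(i)
    model$params[[i]]$transform(xb[i]) , numeric(1))
  names(vals) <- model$base_params
  if (!model$has_forgetting) vals <- c(vals, alpha_f = 0)
  vals
}

#' Fresh learner state
#'
#' Values start at 0 for all options, experience weights at 1 (keeping the
#' EWA update well-defined on the first trial), and hybrid associability at 1.
#'
#' @param n_options Number of options.
#' @return A `learner_state` list with elements `V`, `n`, `a`.
#' @export
new_learner_state <- function(n_options = 3L) {
  structure(list(V = rep(0, n_options), n = rep(1, n_options),
                 a = rep(1, n_options)),
            class = "learner_state")
}

check_outcome <- function(outcome) {
  if (!(length(outcome) == 1L && outcome %in% c(-1, 1)))
    stop("outcome must be -1 or +1")
}

check_unit <- function(x, name) {
  if (!(is.finite(x) && x >= 0 && x <= 1))
    stop(sprintf("%s must lie in [0, 1]", name))
}

#' EWA value update for the chosen option
#'
#' Experience weight `n_c <- n_c * rho + 1`; value
#' `V_c <- (V_c * phi * n_c_old + outcome) / n_c_new`. Unchosen options are
#' untouched. With increasing experience weight the effective learning rate
#' shrinks, so behaviour becomes progressively harder to reverse.
#'
#' @param state A [new_learner_state()].
#' @param choice 1-based option index.
#' @param outcome Feedback, -1 or +1.
#' @param phi Inverse learning rate (decay of previous payoffs), in `[0, 1]`.
#' @param rho Experience decay factor, in `[0, 1]`.
#' @return Updated `learner_state`.
#' @export
ewa_update <- function(state, choice, outcome, phi, rho) {
  check_outcome(outcome); check_unit(phi, "phi"); check_unit(rho, "rho")
  n_old <- state$n[choice]
  n_new <- n_old * rho + 1
  state$V[choice] <- (state$V[choice] * phi * n_old + outcome) / n_new
  state$n[choice] <- n_new
  state
}

#' Decay unchosen options' values toward their initial value
#'
#' Each unchosen value is multiplied by `(1 - alpha_f)`; the chosen option is
#' untouched. `alpha_f = 0` leaves the state unchanged (plain EWA),
#' `alpha_f = 1` resets unchosen values to the initial value 0.
#'
#' @inheritParams ewa_update
#' @param alpha_f Forgetting rate, in `[0, 1]`.
#' @return Updated `learner_state`.
#' @export
forget_unchosen <- function(state, choice, alpha_f) {
  check_unit(alpha_f, "alpha_f")
  idx <- setdiff(seq_along(state$V), choice)
  state$V[idx] <- (1 - alpha_f) * state$V[idx]
  state
}

#' Pearce-Hall hybrid update for the chosen option
#'
#' Prediction error `delta = outcome - V_c`; value
#' `V_c <- V_c + eta * a_c * delta` using the pre-update associability; then
#' associability `a_c <- (1 - kappa) * a_c + kappa * |delta|`, so the
#' effective learning rate tracks recent surprise. Unchosen options are
#' untouched.
#'
#' @inheritParams ewa_update
#' @param eta Learning rate, in `[0, 1]`.
#' @param kappa Associability update rate, in `[0, 1]`.
#' @return Updated `learner_state`.
#' @export
hybrid_update <- function(state, choice, outcome, eta, kappa) {
  check_outcome(outcome); check_unit(eta, "eta"); check_unit(kappa, "kappa")
  delta <- outcome - state$V[choice]
  state$V[choice] <- state$V[choice] + eta * state$a[choice] * delta
  state$a[choice] <- (1 - kappa) * state$a[choice] + kappa * abs(delta)
  state
}

#' Softmax choice probabilities
#'
#' `p_i = exp(beta * V_i) / sum_j exp(beta * V_j)`, evaluated via the
#' log-sum-exp trick.
#'
#' @param values Numeric vector of option values.
#' @param beta Non-negative inverse temperature; 0 gives uniform choice.
#' @return Probability vector summing to 1.
#' @export
softmax_probs <- function(values, beta) {
  if (!all(is.finite(values))) stop("values must be finite")
  if (!(is.finite(beta) && beta >= 0)) stop("beta must be non-negative")
  z <- beta * values
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

#' Construct a single-session record
#'
#' One subject-session: role-coded choices, outcomes, drug label, optional
#' reaction times, and the task configuration that defines trial phases.
#'
#' @param choices Integer vector of role indices (1-based, 1 = "RP").
#' @param outcomes Numeric vector of feedbacks in `{-1, +1}`.
#' @param drug `"placebo"` or `"MPH"`.
#' @param config A [task_config()] (defines `n_options` and phases).
#' @param subject_id Optional subject identifier.
#' @param rt_ms Optional positive reaction times (ms), `NA` allowed.
#' @return A `prl_session` object.
#' @export
prl_session <- function(choices, outcomes, drug = c("placebo", "MPH"),
                        config = task_config(), subject_id = NA,
                        rt_ms = NULL) {
  drug <- match.arg(drug)
  choices <- as.integer(choices)
  stopifnot(length(choices) == length(outcomes))
  if (length(choices) > config$n_trials)
    stop("more trials than the task configuration allows")
  if (any(choices < 1L | choices > config$n_options))
    stop("choice indices out of range")
  if (!all(outcomes %in% c(-1, 1)))
    stop("outcomes must be -1 or +1")
  if (!is.null(rt_ms)) {
    stopifnot(length(rt_ms) == length(choices))
    if (any(rt_ms <= 0, na.rm = TRUE)) stop("reaction times must be positive")
  }
  structure(
    list(subject_id = subject_id, drug = drug, choices = choices,
         outcomes = as.numeric(outcomes),
         phase = trial_phase(config, seq_along(choices)),
         rt_ms = rt_ms, config = config),
    class = "prl_session")
}

#' @export
print.prl_session <- function(x, ...) {
  cat(sprintf("<prl_session> subject %s, %s, %d trials, mean outcome %.2f\n",
              x$subject_id, x$drug, length(x$choices), mean(x$outcomes)))
  invisible(x)
}

# normalize `sessions` to a list of prl_session and check split-model needs
check_sessions <- function(model, sessions) {
  if (inherits(sessions, "prl_session")) sessions <- list(sessions)
  stopifnot(length(sessions) >= 1L,
            all(vapply(sessions, inherits, logical(1), "prl_session")))
  if (!is.null(model$split_param)) {
    drugs <- vapply(sessions, `[[`, character(1), "drug")
    if (!all(c("placebo", "MPH") %in% drugs))
      stop(sprintf("model %s splits '%s' by drug and needs both a placebo and an MPH session",
                   model$name, model$split_param))
  }
  sessions
}

#' Negative log likelihood of one subject's session(s)
#'
#' Sums `-log p(choice_t)` over all trials of all sessions, with the softmax
#' probabilities computed along the model's value trajectory. The learner
#' state is reset at the start of every session (no carry-over across days).
#' For drug-split models the split parameter switches with each session's
#' drug label, and both a placebo and an MPH session must be supplied.
#'
#' @param model A [prl_model()].
#' @param x Unconstrained parameter vector of length `model$n_params`.
#' @param sessions A `prl_session` or list of them (one subject).
#' @param engine `"cpp"` (compiled, default) or `"r"` (reference
#'   implementation built from [ewa_update()], [hybrid_update()],
#'   [forget_unchosen()] and [softmax_probs()]).
#' @return Non-negative scalar.
#' @export
negative_log_likelihood <- function(model, x, sessions,
                                    engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  sessions <- check_sessions(model, sessions)
  stopifnot(length(x) == model$n_params, all(is.finite(x)))
  total <- 0
  for (s in sessions) {
    p <- constrained_params(model, x, s$drug)
    total <- total + if (engine == "cpp") {
      if (model$kind == "ewa")
        nll_ewa_cpp(s$choices, s$outcomes, p[["phi"]], p[["rho"]],
                    p[["beta"]], p[["alpha_f"]], s$config$n_options)
      else
        nll_hybrid_cpp(s$choices, s$outcomes, p[["eta"]], p[["kappa"]],
                       p[["beta"]], p[["alpha_f"]], s$config$n_options)
    } else {
      nll_session_r(model$kind, s, p)
    }
  }
  if (!is.finite(total)) stop("likelihood is not finite")
  total
}

# readable single-session trial loop used by engine = "r"
nll_session_r <- function(kind, s, p) {
  st <- new_learner_state(s$config$n_options)
  nll <- 0
  for (t in seq_along(s$choices)) {
    pr <- softmax_probs(st$V, p[["beta"]])
    c_t <- s$choices[t]
    nll <- nll - log(pr[c_t])
    st <- if (kind == "ewa")
      ewa_update(st, c_t, s$outcomes[t], p[["phi"]], p[["rho"]])
    else
      hybrid_update(st, c_t, s$outcomes[t], p[["eta"]], p[["kappa"]])
    st <- forget_unchosen(st, c_t, p[["alpha_f"]])
  }
  nll
}
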