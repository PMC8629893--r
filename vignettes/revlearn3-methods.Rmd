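---
title: "Models and methods behind revlearn3"
author: "revlearn3 authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind revlearn3}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

revlearn3 analyses a three-option probabilistic reversal learning (PRL) task
performed twice per subject — once under placebo and once under
methylphenidate (MPH), a catecholamine transporter blocker — in a
within-subject cross-over design. This vignette documents the task model, the
learning-model family, the hierarchical inference scheme, the behavioural
statistics, the synthetic cohort generator, and the numerical choices made
where the design was genuinely open.

## The task

On each of 80 trials the participant chooses one of three stimuli and
receives a binary outcome, reward (+1) or punishment (−1). Stimulus roles are
defined by the participant's *first* choice: the first-chosen stimulus
("RP") is rewarded with probability 0.75 during the 40 acquisition trials
and 0.25 afterwards; "PR" carries the mirrored contingency; the neutral
stimulus "NN" is rewarded with probability 0.5 throughout. The neutral
option separates two possible sources of post-reversal perseveration:
failure to let go of the previously rewarded stimulus versus failure to
approach the previously punished one.

`generate_feedback_schedule()` pre-draws the outcome every stimulus *would*
deliver on every trial, so the environment is choice-independent: identical
seeds give comparable environments across agents, and counterfactual
outcomes are well defined. Two modes are provided because published
variants of this paradigm differ in (and rarely fully specify) their
feedback-sequence constraints:

* `exact_ratio` (default): per role and phase the number of rewards is
  exactly `round(p × phase_length)` (30/10, 10/30, 20/20 in the default
  design). For the two reversing roles the arrangement is drawn *uniformly*
  among arrangements containing no run of 5 or more identical outcomes,
  using a dynamic-programming prefix-count sampler (rejection sampling would
  discard almost every draw, since a 30:10 mix almost always contains a
  5-run). Long identical-outcome runs distort probabilistic learning, which
  is why the constraint exists; it is configurable via `max_run`.
* `iid`: independent Bernoulli outcomes, matching the ratios in expectation.

Trial indexing is 1-based in all I/O; trials 1–40 are acquisition, 41–80
reversal (the reversal trial, 41, is the first trial of the new
contingencies). Of the two non-first-chosen stimuli, "PR" is assigned
uniformly at random, as the assignment rule is not otherwise determined.

## The learning-model family

All models share softmax choice,
$p(c_t = i) = \exp(\beta V_{i,t}) / \sum_j \exp(\beta V_{j,t})$, evaluated
with the log-sum-exp trick; $\beta \ge 0$ is the inverse temperature.

**Experience-Weighted Attraction (EWA).** Each option carries a value
$V_c$ (initialised at 0) and an experience weight $n_c$ (initialised at 1,
which keeps the first update well defined). After choosing $c$ and observing
$\lambda_t \in \{-1, +1\}$:

$$n_{c,t+1} = n_{c,t}\,\rho + 1, \qquad
V_{c,t+1} = \frac{V_{c,t}\,\varphi\,n_{c,t} + \lambda_t}{n_{c,t+1}}, \qquad
V_{\sim c,t+1} = V_{\sim c,t}.$$

$\varphi \in [0,1]$ is the decay of previous payoffs — an *inverse* learning
rate (higher $\varphi$, slower updating) — and $\rho \in [0,1]$ governs the
growth of the experience weight. As $n_c$ grows the effective learning rate
shrinks, capturing a progressive reluctance to update well-practised
options, the mechanism of interest for reversal impairments.

**Forgetting (+F).** With three options, unchosen stimuli go unsampled for
longer, so the `+F` variants decay every unchosen value toward its initial
value: $V_{\sim c,t+1} = (1-\alpha_f) V_{\sim c,t}$, $\alpha_f \in [0,1]$.
At $\alpha_f = 0$ the model is exactly the base model (the test suite
asserts bit-level equality of the likelihoods).

**Pearce-Hall hybrid.** The alternative mechanism lets the learning rate
track surprise via an associability $a_c$ (initialised at 1):
$\delta = \lambda_t - V_c$, $V_c \leftarrow V_c + \eta\, a_c\, \delta$,
$a_c \leftarrow (1-\kappa) a_c + \kappa |\delta|$, using the pre-update
associability in the value step. Hybrid parameterisations vary across the
literature; the standard Li/Piray form above is used, with associability
initialised at 1 by the usual convention.

**Drug-split models.** The 2 × 2 base family (EWA/hybrid × ±forgetting) is
fitted jointly across both sessions with fully shared parameters (the state
is reset at each session start; nothing carries over between days). The
winning base model, EWA+F, is then extended by estimating one parameter in
turn separately for placebo and MPH sessions — `EWA+F+dphi`, `+drho`,
`+dalpha_f`, `+dbeta` — each adding exactly one parameter. Choice
probabilities enter one likelihood per subject, with the split parameter
switched by each session's drug label.

**Parameterisation.** All fitting happens on the unconstrained scale:
unit-interval parameters through the standard logistic, $\beta$ through the
exponential, each with a weakly informative Gaussian prior N(0, 10). The
likelihood is implemented in C++ (with an R reference engine built from the
exported single-step update functions; the two are tested against an
independently coded trial loop to 1e-10).

## Inference

**Subject level.** `fit_map()` minimises the negative log posterior by
multi-start BFGS (default 5 restarts; the first start is the prior mean,
the rest are drawn from the prior) and Laplace-approximates the log model
evidence, $-\text{obj} + \tfrac{d}{2}\log 2\pi - \tfrac12 \log\det H$, with
$H$ the central-finite-difference Hessian (fixed relative step $10^{-4}$,
symmetrised; an escalating diagonal ridge is applied — and recorded — in
the rare case $H$ is not positive definite). On a conjugate-Gaussian toy
problem, where the Laplace approximation is exact, mode and evidence match
the closed forms to 1e-8.

**Group level.** `hbi()` implements a random-effects scheme in the spirit of
hierarchical Bayesian model-comparison toolboxes: each model carries a group
Gaussian (diagonal) over unconstrained parameters and the cohort carries a
Dirichlet over model frequencies (prior concentration 1 per model). An EM
loop alternates (i) posterior responsibilities
$r_{nm} \propto \exp(L_{nm} + \mathbb{E}[\ln \pi_m])$ and the Dirichlet
update $\alpha_m = \alpha_0 + \sum_n r_{nm}$ with (ii) responsibility-
weighted re-estimation of group means and variances (subject posterior
variances from the inverse Hessians are included; variances are floored at
$10^{-3}$) and warm-started re-fits of every subject under the updated
priors. The variational free energy of the label mixture is recorded at
every iteration; convergence is declared when it changes by less than
`tol` (default 0.01) per subject. Because the subject-level posteriors are
re-Laplace-approximated each sweep, the trace is not guaranteed monotone in
theory; in practice it is, and the tests require non-decrease up to small
numerical slack.

**Model selection.** From the final evidence matrix: model frequencies
$\alpha/\sum\alpha$; exceedance probabilities by seeded Monte-Carlo Dirichlet
sampling (default $10^6$ draws; an exact Beta tail integral is available for
two models and serves as the test oracle); the Bayes omnibus risk
$\text{BOR} = 1/(1 + e^{F_1 - F_0})$ comparing the mixture free energy
against the null in which all models are equally frequent; and the protected
exceedance probability $\text{pxp} = (1-\text{BOR})\,\text{xp} +
\text{BOR}/K$.

**Parameter statistics.** All downstream parameter analyses (the paired
t-test of $\varphi_{\text{MPH}}$ vs $\varphi_{\text{placebo}}$, Spearman
correlations of $\Delta\varphi$ with working-memory span, impulsivity, and
the drug-induced change in raw performance) deliberately use the *first,
non-hierarchical* estimation step, because hierarchical shrinkage could bias
session differences; the hierarchy is used only for model comparison and
group posteriors. "Raw performance" is summarised per subject and session
as the mean of the two chance-corrected accuracy scores across phases.

## Behavioural statistics

Trials faster than 200 ms are excluded (strictly faster; a 200 ms response
is kept), with the excluded count reported and the unfiltered data left
untouched, so analyses can be run both ways.

Accuracy per subject × session × phase re-evaluates roles per phase ("PR"
is the rewarded stimulus during reversal): `pReward` is the probability of
selecting the currently mostly-rewarded stimulus and avoidance is
`1 − pPunish`. Both are chance-corrected so a uniform random chooser scores
0: `pReward − 1/3` and `(1 − pPunish) − 2/3`. The complementary convention
(`pPunish − 1/3`) is also reported, since "corrected for chance" admits
either; the avoidance-based default keeps the two valence metrics on the
intercept-interpretable scale used by the ANOVA.

The omnibus analysis is the 2 × 2 × 2 within-subject ANOVA — Valence
(reward/avoid) × Phase (acquisition/reversal) × Drug (MPH/placebo) — with
working-memory span and impulsivity as continuous covariates, mean-centered
so the within-subject effects keep their marginal interpretation (the
covariate scale is otherwise left raw; z-scoring would not change any F).
Because every within factor has two levels, each effect reduces to one
subject-wise contrast score, and regressing that score on the centered
covariates yields the exact univariate repeated-measures F tests with
df = (1, n − 1 − 2); the intercept of each contrast regression tests the
within effect itself and the slopes test effect × covariate interactions.
The test suite verifies exact agreement with an independent multivariate
repeated-measures implementation (`car::Anova`) and the equivalence
F = t² against the paired t-test for a single factor. Huynh-Feldt ε is
reported for completeness; it is identically 1 here because two-level
factors cannot violate sphericity, so corrected and uncorrected p
coincide. Designs with more than two levels per within factor are out of
scope and rejected with an informative error. Significant interactions are
broken down by refitting the model within each level of the split factor
(`simple_effects()`), i.e. with within-level error terms rather than a
pooled error.

Stay probabilities condition "choose the same stimulus on the next trial"
on the current outcome's sign, binned by the current trial's phase; chance
level is 1/3.

## The synthetic cohort generator

`generate_cohort()` produces study-shaped data with known ground truth, so
every recovery analysis has a target. Defaults emulate full-scale study
conditions for this paradigm: 102 subjects × 2 sessions ×
80 trials, MPH first for 50 subjects, EWA+F generating parameters drawn
independently per subject on the unconstrained scale with constrained
medians at the winning model's group medians (φ 0.77, ρ 0.63, β 4.23,
α_f 0.35). Group spreads (sd 0.8 on the logit scale for φ, ρ, α_f; 0.5 on
log β) are the package's own choice: the fitted between-subject
interquartile ranges reported for such tasks overstate the generating
spread because they fold in estimation noise, so a moderate spread that
reproduces realistic-looking fitted IQRs was fixed once.

The drug effect is injected on the unconstrained scale — so constraints can
never be violated — as $\Delta\varphi_u = b\,z(\text{WM}) +
\text{noise\_sd}\,\varepsilon$, giving each subject an MPH-session
$\varphi_u = \varphi_{u,\text{placebo}} + \Delta\varphi_u$. The defaults
b = 0.4, noise_sd = 1.0 were calibrated by pilot recovery runs so that the
*fitted* Δφ–WM Spearman correlation at n = 102 lands near 0.2, a realistic
magnitude for covariate-dependent drug effects in this paradigm; the
correlation among *true*
parameters is necessarily larger (≈ 0.37) because estimation noise
attenuates it. Working-memory scores are integers on a listening-span-like
scale (mean 42, sd 12, clamped to 10–80) and impulsivity on a BIS-11-like
total scale (mean 63, sd 9); only their ranks and linear association
matter downstream. Reaction times, used only to exercise the fast-RT
filter, are uniform on 150–2000 ms, so a small fraction falls under the
200 ms threshold.

What the generator deliberately does *not* emulate: within-subject
parameter drift, session-order effects, response-time structure, choice
autocorrelation beyond the model, or correlated group-level parameters
(the true covariance is unknowable from published summaries; independent
Gaussians are the default). Passing recovery tests therefore demonstrate
internal consistency of the pipeline — that the methods recover what this
class of generator planted — not that real data satisfy the model.

## Numerical choices and problem sizes

* Optimiser BFGS, `reltol` 1e-12, 500 iterations; gradients by compiled
  central differences (step $10^{-5}(1+|x|)$), cross-checked against the
  independent R likelihood path to 1e-5. Five restarts by default;
  recovery studies in the tests use 2–3 restarts, which pilot runs showed
  to be sufficient for these 3–5 parameter posteriors.
* The exponential transform of β is clamped at $e^{25}$ so the objective
  stays finite in the far tails, where the prior dominates anyway.
* The optimal-learning-rate analysis sweeps φ with the other parameters at
  the winning-model group medians, and reports accuracy (probability of
  choosing the currently-best stimulus) and mean reward per grid point,
  since either could be the criterion of interest. The accuracy curves are
  flat near their maxima, so besides the raw argmax the package reports a
  smoothed peak — the vertex of a quadratic fitted within ±0.06 of the
  argmax — which is stable against Monte-Carlo noise; the matched
  two-option comparison uses 70:30 contingencies with otherwise identical
  structure. The comparison in the tests uses a 0.80–0.98 grid (step 0.02)
  with 4000 simulated sessions per point.
* Test-suite problem sizes: model- and drug-family recovery use 50-subject
  cohorts with 20 replicates each; parameter recovery 50 subjects;
  the ANOVA calibration check 400 null cohorts of 102 subjects; the
  end-to-end pipeline smoke test 8 subjects. These sizes keep each
  property statistically meaningful while the full suite stays
  desk-runnable.

## Known limitations

* The hybrid model equations follow the standard convention; other
  parameterisations of the surprise-modulated learning rate exist.
* The HBI free energy omits parameter-level hyperprior terms; group
  variances are floored rather than given a conjugate hyperprior. With a
  single model the scheme still yields the expected empirical-Bayes
  shrinkage (tested).
* Group-level parameters are modelled as independent across dimensions.
* No response-time modelling; reaction times exist only for the data-quality
  filter.
* The two-option comparison task is a structural match (70:30, single
  reversal), not a re-implementation of any particular earlier experiment.
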