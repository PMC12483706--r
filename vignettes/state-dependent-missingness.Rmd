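---
title: "Hidden Markov models with state-dependent missingness: methods and design"
author: "mnarhmm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hidden Markov models with state-dependent missingness: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mnarhmm)
```

## The problem

Longitudinal clinical data — for example weekly clinician ratings of symptom
severity in a drug trial — are rarely complete. Patients skip visits or drop
out, and the reasons are often related to how ill they are. If the analysis
ignores this, treating the data as missing at random (MAR), parameter
estimates and patient classifications can be biased: a treatment can look
more (or less) effective than it is because the patients who left are
systematically different from those who stayed.

`mnarhmm` models such data with a hidden Markov model (HMM) in which the
latent state represents the underlying health status, and — crucially — the
*probability that a rating is missing* is itself part of the model and may
depend on the hidden state. Because the state also drives the observed
ratings, this induces a missing-not-at-random (MNAR) mechanism: missingness
carries information about the unobserved severity, and the model uses it.

## The model

For each subject $i$ we observe, at integer occasions $t = 1, \dots, T_i$, a
possibly-missing response $y_{it}$ and its missingness indicator
$m_{it} = 1\{y_{it}\ \text{missing}\}$, plus fully observed covariates
$x_{it}$. A latent state $S_{it} \in \{1,\dots,K\}$ follows a first-order
Markov chain. The four submodels are:

* **Initial state**: multinomial logit,
  $P(S_{i1} = k) \propto \exp(x_{i1}^\top \beta^{\pi}_k)$, with
  $\beta^{\pi}_1 = 0$ for identification.
* **Transitions**: per origin state $j$ a multinomial logit over the next
  state, $P(S_{it} = k \mid S_{i,t-1} = j) \propto
  \exp(x_{i,t-1}^\top \beta^{A}_{jk})$, reference column $k = 1$ fixed at 0.
  The matrix acting between $t-1$ and $t$ is evaluated at the covariates of
  the *from* occasion $t-1$; the timing convention is arbitrary in
  principle, so we fix it and document it.
* **Emissions**: Gaussian, $y_{it} \mid S_{it} = k \sim
  N(x_{it}^\top \beta^{y}_k, \sigma_k^2)$. Ordinal severity ratings are
  treated as continuous, which pseudo-residual checks can (and should)
  interrogate.
* **Missingness**: logistic,
  $P(m_{it} = 1 \mid S_{it} = k) = \mathrm{logit}^{-1}(x_{it}^\top
  \beta^{m}_k)$.

The per-row observation density is the product of the response factor and
the missingness factor. A missing response contributes a response factor of
exactly 1 — the occasion stays in the likelihood so that state probabilities
propagate across unobserved visits — while its indicator still contributes
$p_k(x)$ under the MNAR channel. Three channel modes are supported:

* `absent` (MAR): the indicator does not enter the likelihood at all.
  Standard ignorable-missingness HMM.
* `state_dependent` (MNAR): one logistic submodel per state.
* `state_shared`: one submodel common to all states. Missingness is then
  uninformative about the state, so this is the MAR-equivalent *within* the
  joint likelihood of $(y, m)$ — and therefore the correct null model for
  testing state dependence (the MAR and MNAR likelihoods themselves are not
  comparable, being defined over different variables).

When the missingness submodel is shared across states, the joint
log-likelihood separates exactly into the MAR log-likelihood plus the
Bernoulli log-likelihood of the indicators; the test suite asserts this
identity, which is the ignorability property in computable form.

## Estimation

Parameters are estimated by EM (Baum–Welch). The E-step runs scaled
forward–backward recursions (implemented in C++): forward and backward
variables are renormalized at every step and the log normalizers accumulated,
so series of arbitrary length cannot underflow, and the total log-likelihood
is the sum of log normalizers. The expected complete-data log-likelihood
splits into four weighted likelihoods, so the M-step is four weighted fits:

* initial-state multinomial logit on the $t=1$ rows with $\gamma$ weights;
* transition multinomial logit per origin state on from-occasion design rows
  with $\xi$ weights;
* Gaussian regression per state on the observed-response rows with $\gamma$
  weights, $\hat\sigma_k = \sqrt{\sum w e^2 / \sum w}$ (the ML form, not the
  unbiased one);
* logistic missingness fit per state on all rows with $\gamma$ weights
  (pooled over states in shared mode — since $\sum_k \gamma = 1$ per row,
  that pooled fit collapses to a unit-weight logistic regression).

Intercept-only multinomial and logistic M-steps use their closed forms
(logits of weighted proportions); covariate designs go through IRLS
(`stats::glm.fit`) and `nnet::multinom`. Missing rows contribute no emission
information, only transition and missingness information.

### Numerical choices

* **Convergence**: absolute log-likelihood change below `tolerance`
  (default `1e-6`), capped at `max_iterations` (default 500).
  Non-convergence sets a flag rather than erroring.
* **Separation**: early EM iterations can put essentially zero posterior
  weight on a category. Fitted probabilities inside the logistic and
  multinomial M-steps are clipped to `[1e-10, 1 - 1e-10]` and coefficients
  capped at $|15|$ (odds ratios beyond $e^{15}$ are not distinguishable
  here). Each cap raises a classed warning; `em_fit()` aggregates these into
  a single count per fit.
* **Degenerate states** (posterior mass numerically zero) raise an error
  suggesting re-initialization instead of silently renormalizing; likewise a
  row at which every state has zero density raises an underflow error naming
  the series and position.
* **Viterbi ties** break toward the lowest state index (strict-inequality
  argmax), making decoding deterministic.
* **Start values**: initial and transition probabilities are drawn from flat
  Dirichlet(1, …, 1) distributions (the flat concentration is a fixed
  choice) and converted to intercepts; emission and missingness parameters
  are set by weighted fits against per-row state probabilities drawn from
  the same Dirichlet. `multistart_fit()` derives per-start seeds
  deterministically from one master seed and returns the best final
  log-likelihood, keeping all start log-likelihoods for inspection.

## Diagnostics

* **Model selection across state counts** uses AIC/BIC with the
  free-parameter count (reference-state coefficients excluded, plus the $K$
  standard deviations). The BIC sample size is the total number of rows
  (time points) across series by default; `n_mode = "series"` is available
  since the effective sample size of longitudinal data is debatable.
* **MAR vs MNAR** is decided by a likelihood-ratio test of the state-shared
  restriction against state-dependent missingness
  ($\mathrm{df} = (K-1)\,p_\text{miss}$). AIC/BIC must *not* be compared
  between the `absent` and MNAR channels, as they target different
  likelihoods. The usual regularity caveats (estimates near the boundary,
  label permutation) apply to the chi-squared reference; the test is
  implemented in its standard form and the caveat documented rather than
  "fixed".
* **Pseudo-residuals**: for each observed response,
  $u = \sum_k w_k \Phi((y - \mu_k)/\sigma_k)$ mapped to standard-Normal
  quantiles, with normalized weights
  $w_k \propto P(S_t = k \mid \text{everything except } y_t)$ — the
  forward-predicted state mass, times the row's missingness-indicator
  factor under MNAR channels, times the backward variable. The choice of
  conditioning set matters: weights that *include* the assessed response
  (plain smoothed probabilities) concentrate $u$ around 0.5 and fail the
  uniformity property they are meant to deliver, which we verified by
  simulation before fixing the full-conditional definition; one-step-ahead
  (forecast) weights are the other coherent choice and are out of scope.
  Under a correctly specified model $u$ is uniform; the suite checks this
  by probability-integral-transform simulation.
* **Standard errors** come from a central finite-difference Hessian of the
  log-likelihood at the estimates (relative step `1e-4`, absolute floor
  `1e-5`), $\mathrm{SE} = \sqrt{\mathrm{diag}(-H)^{-1}}$, with
  pseudo-inverse fallback and per-parameter flags when the Hessian is not
  positive definite.

## The synthetic-data generator

`scenario_registry()` pins ten benchmark conditions used across the tests
and the acceptance script: a 3-state chain with Gaussian emissions, means
$(-1, 0, 1)$, "low" (SD 0.5) and "high" (SD 1.0) variance versions, and six
missingness mechanisms (none; per-state probabilities $(0.1, 0.25, 0.5)$;
shared 0.25; logistic in the true response; logistic in time — attrition;
per-state intercepts with time slopes). Defaults are 50 series of length 20
(length 50 for the response-value and attrition conditions, so attrition has
room to bite), with the baseline transition matrix set to self-transition
0.75 — an expected run length of 4 occasions — and variants with uniform
initial probabilities, less persistent (0.5), and state-dependent
persistence (0.80/0.90/0.95).

Two calibration notes:

* The response-value mechanism uses logistic coefficients $(-1.4, 1.4)$.
  These were frozen by numeric integration of
  $E[\mathrm{logit}^{-1}(b_0 + b_1 Y) \mid S = k]$ over each state's
  Gaussian, so that the implied per-state expected missingness is
  approximately 6.9%, 21.9%, and exactly 50% — i.e., missingness rises
  steeply with severity while remaining state-free given the true value.
  A nearby candidate, $(-1.25, 1.25)$, implies 8.8/24.0/50.0% and was
  rejected on that basis.
* The attrition mechanism uses $(-5, 0.125)$: missingness is 0.008 at
  occasion 1 and 0.777 at occasion 50, spanning the negligible-to-dominant
  range over one series.

What the generator emulates: state-driven Gaussian ratings, geometric state
sojourns, and the main missingness taxonomies (state-dependent,
state-independent, value-dependent, time-dependent). What it does not:
ordinal/bounded ratings (real severity scales are discrete and censored at
the ends), covariate-dependent transitions, monotone dropout (missingness
here is intermittent — once-missing subjects can return), and
between-subject heterogeneity beyond the hidden state. Passing tests on
these scenarios therefore validate the estimation machinery and the
MAR/MNAR contrasts, not the adequacy of a Gaussian HMM for any particular
real instrument.

## The simulation study protocol

`run_simulation_study()` reproduces the benchmarking protocol: per
replicate, simulate a dataset, fit each requested model by EM *started at
the generating values* (we are interested in the quality of estimates at
the global maximum, not in start-value search; multistart exists for real
applications), Viterbi-decode, and score. Missingness submodels the
generator does not parameterize directly start at empirical rates. Reported
per parameter, on the probability scale for initial/transition
probabilities (as benchmark tables conventionally print them) and raw scale
for means and SDs: mean, SD, and mean absolute error (MAE) across
replicates, the per-parameter MNAR/MAR MAE ratio, and its average over the
18 shared parameters. Replicates whose fit fails or hits the iteration cap
are dropped from that model's aggregates with counts reported.

Default problem sizes are chosen so the full suite stays comfortably
desk-scale: 100 replicates of 50 × 20 observations with EM tolerance `1e-5`
and a 200-iteration cap for study fits (estimate movement at that tolerance
is far below Monte-Carlo error at 100 replicates); 1000-replicate runs are a
matter of passing `n_datasets = 1000`.

Two oracles contextualize recovery percentages:
`mixture_accuracy_oracle()` gives the best achievable static (i.i.d.
mixture over response and indicator, stationary weights) classification
accuracy, and `hmm_accuracy_oracle()` the Viterbi recovery when decoding
with the *true* parameters under either the MAR or MNAR view — upper
reference points for fitted-model recovery.

## The clinical-trial application plan

`application_config()` encodes the intended real-data analysis: MAR and
MNAR models with 2–5 states; treatment arm (`drug`) on the initial-state
and transition submodels (also at baseline, to absorb pre-existing
differences); intercept-only emission means (the states themselves carry
severity); and missingness depending on the state plus `week` and the
main-occasion indicator `main` — the two predictors a state-free logistic
screen (`missingness_screen()`) flags in such designs. State counts are
compared by BIC within each channel; the MAR-vs-MNAR question is answered
by the LRT of the shared-missingness restriction at the selected state
count. The function only executes when pointed at a local copy of the trial
table; nothing is downloaded.

## Known limitations

* Label switching: likelihoods are invariant to state permutation. Fits
  started at generating values keep the generating order; random-start fits
  may not, which is why `state_recovery_rate()` offers optional
  permutation alignment and the study protocol does not need it.
* The LRT's chi-squared reference is approximate when fitted missingness
  probabilities sit near 0 or 1.
* The EM finds local maxima; multistart mitigates but does not guarantee.
* Univariate responses only; the conditional-independence factorization
  extends to multivariate responses but is not implemented.
* Missing covariates are a hard error by design: the model conditions on
  covariates and makes no attempt to model them.
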