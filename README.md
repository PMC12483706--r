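# mnarhmm

Hidden Markov models for longitudinal data whose response may be **missing
not at random (MNAR)**, with the probability of a missing observation
depending on the *hidden state* and on covariates.

## Why

Longitudinal clinical studies — e.g., weekly severity ratings in a drug
trial — suffer attrition and intermittent missingness, and the patients who
stop providing data are often systematically different from those who
continue. Standard HMM software treats missing responses as ignorable
(MAR). When missingness actually tracks the latent health state, that
assumption biases both the parameter estimates and the classification of
patients into states. `mnarhmm` makes the missingness indicator part of the
model: a per-state logistic regression
$P(m_{it}=1 \mid S_{it}=k) = \mathrm{logit}^{-1}(x_{it}^\top\beta^m_k)$
sits alongside the multinomial-logit initial-state and transition submodels
and the Gaussian emission submodel
$y_{it}\mid S_{it}=k \sim N(x_{it}^\top\beta^y_k,\ \sigma_k^2)$.
A missing response contributes a response factor of 1 (the occasion stays in
the chain), while its indicator still contributes its Bernoulli mass — so
missingness informs the state posterior instead of being thrown away.

The package provides:

* scaled forward–backward smoothing, log-likelihood, and Viterbi decoding
  under MAR and MNAR observation channels (recursions in C++);
* Baum–Welch EM with weighted GLM M-steps, random Dirichlet starts, and
  multistart (`em_fit()`, `multistart_fit()`);
* diagnostics: AIC/BIC, the likelihood-ratio test of the *state-shared*
  missingness restriction (the correct MAR-vs-MNAR comparison — AIC/BIC are
  not comparable across channels), full-conditional pseudo-residuals, and
  finite-difference standard errors;
* a simulation framework (`scenario_registry()`, `simulate_dataset()`,
  `run_simulation_study()`) benchmarking MAR against MNAR models under ten
  canonical missingness scenarios, with mixture and true-parameter decoding
  oracles;
* a long-format CSV data model and a thin CLI
  (`inst/cli/mnarhmm.R`: `simulate` / `fit` / `decode` / `compare` /
  `residuals`).

## Worked example

Simulate the state-*independent* missingness benchmark (3 Gaussian states,
means −1/0/1, SD 0.5, self-transition 0.75, every observation missing with
probability 0.25), fit the state-dependent MNAR model, and test whether
missingness is state-dependent:

```r
library(mnarhmm)

cfg <- scenario_registry("sim2")
sim <- simulate_dataset(cfg, seed = 42)
sim$dataset
#> Longitudinal HMM dataset: 50 series, 1000 rows, 242 missing responses

spec <- model_spec_for(cfg, "mnar_state")
ctrl <- em_controls(max_iterations = 200, tolerance = 1e-5)
fit  <- em_fit(sim$dataset, spec, start_at_truth(cfg, spec, sim$dataset), ctrl)
fit
#> HMM fit: K = 3 | missingness: state_dependent
#>   logLik = -1473.9294 | iterations = 72 | converged = TRUE | free parameters = 17

round(fit$params$emission_coefs[, 1], 3)   # state means   (truth -1, 0, 1)
#> [1] -0.990 -0.114  0.949
round(plogis(fit$params$missingness_coefs[, 1]), 3)  # per-state P(missing)
#> [1] 0.246 0.173 0.299

dec <- viterbi_decode(sim$dataset, fit$params)
state_recovery_rate(sim$truth$true_state, dec$map_state)
#> [1] 79.7

red  <- em_fit(sim$dataset, constrain_mar(spec),
               start_at_truth(cfg, constrain_mar(spec), sim$dataset), ctrl)
lr_test(red, fit)
#> Likelihood-ratio test: chi-squared = 2.65926 , df = 2 , p = 0.2646
```

Read: the fitted state means and dispersions recover the truth; the three
per-state missingness probabilities scatter around the generating shared
rate 0.25; and the likelihood-ratio test correctly finds no evidence that
missingness is state-dependent in these (state-free) data. On the
state-dependent benchmark `"sim1"` the same test rejects, the MNAR model's
parameter MAE beats the MAR model's, and its decoded states recover more of
the truth — run `run_simulation_study("sim1", n_datasets = 100, seed = 1)`
to reproduce the full comparison table.

The methods vignette (`vignettes/state-dependent-missingness.Rmd`) documents
the model, the EM details, all numerical choices, the benchmark scenario
calibration, and known limitations.

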