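test_that("weighted Gaussian fit matches closed forms", {
  X <- matrix(1, 2, 1)
  f <- weighted_gaussian_fit(c(0, 2), c(1, 1), X)
  expect_equal(unname(f$coefficients), 1)
  expect_equal(f$sigma, 1)
  f2 <- weighted_gaussian_fit(c(0, 4), c(3, 1), X)
  expect_equal(unname(f2$coefficients), 1)
  expect_equal(f2$sigma, sqrt(3))
  # equal weights reduce to ordinary least squares
  set.seed(1)
  y <- rnorm(20)
  X2 <- cbind(1, rnorm(20))
  f3 <- weighted_gaussian_fit(y, rep(2, 20), X2)
  expect_equal(unname(f3$coefficients), unname(coef(lm(y ~ X2[, 2]))),
               tolerance = 1e-10)
  expect_error(weighted_gaussian_fit(y, rep(1, 20), cbind(X2, X2[, 2])),
               "collinear")
  expect_error(weighted_gaussian_fit(y, rep(0, 20), X2), "degenerate")
})

test_that("weighted logistic fit matches the weighted-mean closed form", {
  X <- matrix(1, 4, 1)
  b <- weighted_logistic_fit(c(1, 0, 0, 0), rep(1, 4), X)
  expect_equal(unname(as.numeric(b)), log(1 / 3), tolerance = 1e-9)
  b2 <- weighted_logistic_fit(c(1, 0), c(1, 3), matrix(1, 2, 1))
  expect_equal(unname(as.numeric(b2)), log(1 / 3), tolerance = 1e-9)
  # all-zero outcome: separation fallback caps the intercept with a warning
  expect_warning(b3 <- weighted_logistic_fit(c(0, 0, 0), rep(1, 3),
                                             matrix(1, 3, 1)),
                 "capped")
  expect_equal(unname(as.numeric(b3)), -15)
  # with a covariate the IRLS route agrees with glm
  set.seed(2)
  x <- rnorm(50)
  m <- rbinom(50, 1, plogis(-0.5 + x))
  w <- runif(50, 0.5, 2)
  b4 <- weighted_logistic_fit(m, w, cbind(1, x))
  ref <- suppressWarnings(coef(glm(m ~ x, family = binomial, weights = w)))
  expect_equal(unname(as.numeric(b4)), unname(ref), tolerance = 1e-6)
})

test_that("weighted multinomial fit matches closed-form proportions", {
  X <- matrix(1, 3, 1)
  cf <- weighted_multinomial_fit(1:3, c(0.5, 0.25, 0.25), X)
  expect_equal(cf[, 1], c(0, log(0.5), log(0.5)), tolerance = 1e-9)
  # uniform weighted frequencies give all-zero coefficients
  cf0 <- weighted_multinomial_fit(1:3, rep(1, 3), X)
  expect_equal(cf0[, 1], rep(0, 3))
  # K = 2 reduces to the logistic fit of the category-2 indicator
  m <- c(0, 1, 1, 0, 1)
  w <- c(1, 2, 1, 1, 0.5)
  cf2 <- weighted_multinomial_fit(m + 1, w, matrix(1, 5, 1))
  b <- weighted_logistic_fit(m, w, matrix(1, 5, 1))
  expect_equal(cf2[2, 1], unname(as.numeric(b)), tolerance = 1e-8)
  # never-observed category triggers the clipping fallback with a warning
  expect_warning(cfz <- weighted_multinomial_fit(c(1, 1, 2), rep(1, 3), X,
                                                 n_categories = 3),
                 "zero weight")
  expect_equal(cfz[3, 1], -15)
  # K = 1 has no free coefficients
  expect_equal(weighted_multinomial_fit(rep(1, 3), rep(1, 3), X,
                                        n_categories = 1),
               matrix(0, 1, 1))
})

test_that("a single EM step lands on closed-form MLEs when K = 1", {
  y <- c(0.4, NA, 1.3, -0.2, NA, 0.9)
  ds <- long_dataset(data.frame(id = rep(c("a", "b"), each = 3),
                                time = rep(1:3, 2), y = y))
  yo <- y[!is.na(y)]
  # MAR: Gaussian MLE on the observed responses
  spec <- hmm_spec(1)
  st <- params_from_probs(spec, 1, matrix(1), means = 5, sds = 3)
  s1 <- em_step(ds, st)
  expect_equal(unname(s1$params$emission_coefs[1, 1]), mean(yo), tolerance = 1e-10)
  expect_equal(s1$params$emission_sd[1],
               sqrt(mean((yo - mean(yo))^2)), tolerance = 1e-10)
  # MNAR: missingness intercept is the logit of the overall missing fraction
  spec2 <- hmm_spec(1, missingness_mode = "state_dependent")
  st2 <- params_from_probs(spec2, 1, matrix(1), means = 5, sds = 3,
                           missingness_probs = 0.5)
  s2 <- em_step(ds, st2)
  expect_equal(unname(s2$params$missingness_coefs[1, 1]), qlogis(2 / 6),
               tolerance = 1e-10)
})

test_that("EM never decreases the log-likelihood", {
  for (seed in 1:4) {
    set.seed(seed)
    cfg <- scenario_config(n_series = 10, series_length = 10,
                           init_probs = c(0.5, 0.5),
                           transition = matrix(c(0.8, 0.2, 0.3, 0.7), 2, 2,
                                               byrow = TRUE),
                           emission_means = c(-1, 1), emission_sds = c(1, 1),
                           missingness_kind = "state",
                           missingness_params = c(0.1, 0.4))
    sim <- simulate_dataset(cfg, seed = seed)
    spec <- model_spec_for(cfg, "mnar_state")
    start <- generate_start_values(sim$dataset, spec, seed = seed + 100)
    fit <- em_fit(sim$dataset, spec, start,
                  em_controls(max_iterations = 40, tolerance = 1e-8))
    expect_true(all(diff(fit$trace) >= -1e-8))
  }
})

test_that("EM started at the generating values converges cleanly", {
  cfg <- scenario_registry("sim2")
  cfg$n_series <- 30
  sim <- simulate_dataset(cfg, seed = 5)
  spec <- model_spec_for(cfg, "mnar_state")
  fit <- em_fit(sim$dataset, spec, start_at_truth(cfg, spec, sim$dataset),
                em_controls(max_iterations = 200, tolerance = 1e-5))
  expect_true(fit$converged)
  expect_true(all(diff(fit$trace) >= -1e-8))
  expect_equal(fit$n_free_parameters, 17)  # 2 + 6 + 3 + 3 + 3
  # estimated state order matches the generating order: means stay sorted
  expect_true(all(diff(fit$params$emission_coefs[, 1]) > 0))
})

test_that("start-value generation is deterministic and valid", {
  cfg <- scenario_registry("sim1")
  cfg$n_series <- 10
  sim <- simulate_dataset(cfg, seed = 3)
  spec <- model_spec_for(cfg, "mnar_state")
  a <- generate_start_values(sim$dataset, spec, seed = 9)
  b <- generate_start_values(sim$dataset, spec, seed = 9)
  expect_identical(a, b)
  pr <- initial_state_probs(1, a)
  expect_equal(sum(pr), 1)
  expect_true(all(pr >= 0))
  A <- transition_matrix(1, a)
  expect_equal(rowSums(A), rep(1, 3))
  expect_true(all(a$emission_sd > 0))
})

test_that("multistart returns the best start and matches em_fit at one start", {
  set.seed(10)
  cfg <- scenario_config(n_series = 20, series_length = 10,
                         init_probs = c(0.5, 0.5),
                         transition = matrix(c(0.9, 0.1, 0.1, 0.9), 2, 2,
                                             byrow = TRUE),
                         emission_means = c(-4, 4), emission_sds = c(0.5, 0.5),
                         missingness_kind = "none")
  sim <- simulate_dataset(cfg, seed = 21)
  spec <- hmm_spec(2)
  ctrl1 <- em_controls(max_iterations = 300, tolerance = 1e-6, n_starts = 1,
                       seed = 4)
  ms1 <- multistart_fit(sim$dataset, spec, ctrl1)
  set.seed(4)
  sd1 <- sample.int(.Machine$integer.max %/% 2, 1)
  direct <- em_fit(sim$dataset, spec,
                   generate_start_values(sim$dataset, spec, seed = sd1), ctrl1)
  expect_equal(ms1$log_likelihood, direct$log_likelihood)
  ctrl <- em_controls(max_iterations = 300, tolerance = 1e-6, n_starts = 10,
                      seed = 4)
  ms <- multistart_fit(sim$dataset, spec, ctrl)
  lls <- ms$start_logliks[!is.na(ms$start_logliks)]
  expect_true(all(ms$log_likelihood >= lls - 1e-10))
  # well-separated states: most starts find the same maximum
  expect_gte(mean(abs(lls - max(lls)) < 1e-4), 0.8)
})

test_that("fits serialize to JSON and back out numerically intact", {
  ds <- long_dataset(data.frame(id = 1, time = 1:6,
                                y = c(0.1, NA, 0.4, 0.5, NA, 0.2)))
  spec <- hmm_spec(1, missingness_mode = "state_dependent")
  fit <- em_fit(ds, spec, params_from_probs(spec, 1, matrix(1), 0, 1, 0.5),
                em_controls(max_iterations = 20, tolerance = 1e-8))
  js <- fit_to_json(fit)
  parsed <- jsonlite::fromJSON(js)
  expect_equal(parsed$log_likelihood, fit$log_likelihood)
  expect_equal(parsed$spec$n_states, 1)
})
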