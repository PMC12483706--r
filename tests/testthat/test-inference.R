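make_dataset <- function(y, time = seq_along(y), id = rep("a", length(y))) {
  long_dataset(data.frame(id = id, time = time, y = y))
}

test_that("observation densities combine Gaussian and Bernoulli factors", {
  ds <- make_dataset(c(0.3, NA))
  # MAR channel: missing rows contribute exactly 1
  mar <- params_from_probs(hmm_spec(2), c(0.5, 0.5), matrix(0.5, 2, 2),
                           means = c(0, 1), sds = c(1, 1))
  d <- observation_densities(ds, mar)
  expect_equal(d[2, ], c(1, 1))
  expect_equal(d[1, 1], dnorm(0.3, 0, 1))
  # MNAR channel: multiply by the missingness mass
  mnar <- params_from_probs(hmm_spec(2, missingness_mode = "state_dependent"),
                            c(0.5, 0.5), matrix(0.5, 2, 2),
                            means = c(0.3, 1), sds = c(1, 1),
                            missingness_probs = c(0.25, 0.5))
  d2 <- observation_densities(ds, mnar)
  expect_equal(d2[2, 2], 0.5)                      # missing row, p = 0.5
  expect_equal(d2[1, 1], dnorm(0, 0, 1) * 0.75)    # y at the state mean
  expect_equal(d2[1, 1], 0.29920, tolerance = 1e-4)
  expect_equal(observation_density(ds, 2, 2, mnar), 0.5)
  bad <- mnar
  bad$emission_sd[1] <- -1
  expect_error(observation_densities(ds, bad), "sd must be")
})

test_that("multinomial-logit probabilities follow the softmax closed form", {
  sp <- hmm_spec(3)
  zero <- params_from_probs(sp, rep(1/3, 3), matrix(1/3, 3, 3),
                            means = 1:3, sds = rep(1, 3))
  expect_equal(initial_state_probs(1, zero), rep(1/3, 3))
  expect_equal(transition_matrix(1, zero), matrix(1/3, 3, 3))
  # intercepts (log 2, 0) for states 2, 3 against reference state 1
  p <- hmm_params(sp,
                  init_coefs = matrix(c(0, log(2), 0), 3, 1),
                  transition_coefs = array(0, c(3, 3, 1)),
                  emission_coefs = matrix(1:3, 3, 1),
                  emission_sd = rep(1, 3))
  expect_equal(initial_state_probs(1, p), c(0.25, 0.5, 0.25))
  # K = 1 degenerates to probability 1
  one <- params_from_probs(hmm_spec(1), 1, matrix(1), 0, 1)
  expect_equal(initial_state_probs(1, one), 1)
  # overflow guard: huge linear predictors stay on the simplex
  big <- hmm_params(sp,
                    init_coefs = matrix(c(0, 2000, -2000), 3, 1),
                    transition_coefs = array(0, c(3, 3, 1)),
                    emission_coefs = matrix(1:3, 3, 1),
                    emission_sd = rep(1, 3))
  pr <- initial_state_probs(1, big)
  expect_false(anyNA(pr))
  expect_equal(sum(pr), 1)
})

test_that("scaled recursions match the exhaustive-path oracle", {
  for (mode in c("absent", "state_dependent")) {
    inst <- random_instance(K = 2, Tlen = 4, mode = mode, seed = 7)
    oi <- oracle_inputs(inst)
    or <- oracle_fb(oi$dens, oi$pi0, oi$A_list)
    fb <- forward_backward(inst$dataset, inst$params)
    expect_equal(fb$log_likelihood, or$loglik, tolerance = 1e-12)
    expect_equal(unname(fb$gamma), or$gamma, tolerance = 1e-12)
    expect_equal(fb$xi[[1]], or$xi, tolerance = 1e-12)
    dec <- viterbi_decode(inst$dataset, inst$params)
    expect_equal(dec$map_state, or$viterbi)
  }
})

test_that("posterior invariants hold on random instances", {
  for (seed in 1:5) {
    inst <- random_instance(K = 3, Tlen = 6, mode = "state_dependent",
                            seed = seed)
    fb <- forward_backward(inst$dataset, inst$params)
    expect_lt(max(abs(rowSums(fb$gamma) - 1)), 1e-10)
    x <- fb$xi[[1]]
    expect_lt(max(abs(apply(x, 1, sum) - 1)), 1e-10)
    # marginalizing xi over the next state reproduces gamma at the "from" row
    marg <- apply(x, c(1, 2), sum)
    expect_lt(max(abs(marg - fb$gamma[1:5, ])), 1e-10)
  }
})

test_that("single-state and all-missing degenerate cases have closed forms", {
  ds <- make_dataset(c(-0.2, 0.4, 1.1))
  one <- params_from_probs(hmm_spec(1), 1, matrix(1), means = 0.5, sds = 1.2)
  fb <- forward_backward(ds, one)
  expect_equal(unname(fb$gamma), matrix(1, 3, 1))
  expect_equal(fb$log_likelihood, sum(dnorm(c(-0.2, 0.4, 1.1), 0.5, 1.2, log = TRUE)))
  # MAR model, fully missing series: every density factor is 1
  dsm <- make_dataset(c(NA, NA, NA))
  mar <- params_from_probs(hmm_spec(2), c(0.3, 0.7), matrix(0.5, 2, 2),
                           means = c(0, 1), sds = c(1, 1))
  expect_equal(log_likelihood(dsm, mar), 0)
})

test_that("likelihood is additive over series", {
  y <- c(0.1, NA, 0.8, 1.4)
  ds1 <- make_dataset(y)
  ds2 <- long_dataset(data.frame(id = rep(c("a", "b"), each = 4),
                                 time = rep(1:4, 2), y = c(y, y)))
  p <- params_from_probs(hmm_spec(2, missingness_mode = "state_dependent"),
                         c(0.4, 0.6), matrix(c(0.8, 0.2, 0.3, 0.7), 2, 2,
                                             byrow = TRUE),
                         means = c(0, 1), sds = c(0.7, 0.9),
                         missingness_probs = c(0.2, 0.4))
  expect_equal(log_likelihood(ds2, p), 2 * log_likelihood(ds1, p),
               tolerance = 1e-12)
})

test_that("MNAR likelihood factorizes when missingness is state-free", {
  inst <- random_instance(K = 3, Tlen = 8, mode = "state_dependent", seed = 11)
  p <- inst$params
  # force the missingness channel to be identical over states
  p$missingness_coefs[] <- qlogis(0.3)
  m <- inst$dataset$frame$.miss
  bern <- sum(m * log(0.3) + (1 - m) * log(0.7))
  mar_params <- p
  mar_params$spec <- hmm_spec(3, missingness_mode = "absent")
  mar_params$missingness_coefs <- NULL
  ll_mar <- log_likelihood(inst$dataset, mar_params)
  expect_equal(log_likelihood(inst$dataset, p), ll_mar + bern, tolerance = 1e-10)
  # the MAR likelihood is invariant to the (absent) missingness channel
  p2 <- p
  p2$missingness_coefs[] <- qlogis(0.8)
  expect_equal(log_likelihood(inst$dataset, p2) -
                 sum(m * log(0.8) + (1 - m) * log(0.2)),
               ll_mar, tolerance = 1e-10)
})

test_that("Viterbi respects deterministic structure and decodes missing rows", {
  one <- params_from_probs(hmm_spec(1), 1, matrix(1), 0, 1)
  ds <- make_dataset(c(0.1, NA, 0.5))
  expect_equal(viterbi_decode(ds, one)$map_state, rep(1, 3))
  # identity transitions with all initial mass on state 2
  p <- params_from_probs(hmm_spec(3), c(1e-12, 1 - 2e-12, 1e-12), diag(3),
                         means = c(-1, 0, 1), sds = rep(10, 3))
  dec <- viterbi_decode(ds, p)
  expect_equal(dec$map_state, rep(2, 3))
  expect_true(all(c("gamma_1", "gamma_2", "gamma_3") %in% names(dec)))
})

test_that("an all-states-zero density row raises an underflow error", {
  ds <- make_dataset(c(0.2, 1e6))
  p <- params_from_probs(hmm_spec(2), c(0.5, 0.5), matrix(0.5, 2, 2),
                         means = c(0, 1), sds = c(0.1, 0.1))
  expect_error(forward_backward(ds, p), "underflow")
})
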