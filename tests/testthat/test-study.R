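test_that("state recovery scoring counts matches and can align labels", {
  expect_equal(state_recovery_rate(c(1, 2, 3), c(1, 2, 3)), 100)
  expect_equal(state_recovery_rate(c(1, 2, 3, 1), c(1, 2, 3, 3)), 75)
  # permuted labels recover fully with alignment on
  truth <- c(1, 1, 2, 3, 2, 1, 3)
  perm <- c(2, 2, 3, 1, 3, 2, 1)
  expect_lt(state_recovery_rate(truth, perm), 100)
  expect_equal(state_recovery_rate(truth, perm, align = TRUE), 100)
  expect_error(state_recovery_rate(1:3, 1:4), "differ in length")
  # independent uniform sequences agree at chance level
  set.seed(6)
  a <- sample.int(3, 30000, replace = TRUE)
  b <- sample.int(3, 30000, replace = TRUE)
  expect_equal(state_recovery_rate(a, b), 100 / 3, tolerance = 0.03)
})

test_that("accuracy oracles respect their degenerate limits", {
  k1 <- scenario_config(n_series = 5, series_length = 10, init_probs = 1,
                        transition = matrix(1), emission_means = 0,
                        emission_sds = 1, missingness_kind = "none")
  expect_equal(mixture_accuracy_oracle(k1, n_points = 100), 100)
  # near-deterministic emissions, no missingness: mixture oracle ~ 100
  sep <- scenario_config(n_series = 5, series_length = 10,
                         init_probs = rep(1/3, 3),
                         transition = matrix(1/3, 3, 3),
                         emission_means = c(-10, 0, 10),
                         emission_sds = rep(1e-3, 3),
                         missingness_kind = "none")
  expect_gt(mixture_accuracy_oracle(sep, n_points = 2000), 99.9)
  # identical emissions and missingness over 3 equally weighted states: chance
  flat <- scenario_config(n_series = 5, series_length = 10,
                          init_probs = rep(1/3, 3),
                          transition = matrix(1/3, 3, 3),
                          emission_means = rep(0, 3),
                          emission_sds = rep(1, 3),
                          missingness_kind = "shared",
                          missingness_params = 0.25)
  expect_equal(mixture_accuracy_oracle(flat, n_points = 50000), 100 / 3,
               tolerance = 0.03)
  # near-deterministic chain with distinct means: Viterbi oracle ~ 100
  det <- scenario_config(n_series = 10, series_length = 10,
                         init_probs = c(0.5, 0.3, 0.2),
                         transition = diag(3) * 0.997 + 0.001,
                         emission_means = c(-5, 0, 5),
                         emission_sds = rep(0.1, 3),
                         missingness_kind = "none")
  expect_gt(hmm_accuracy_oracle(det, n_datasets = 3), 99)
})

test_that("state-dependent missingness is informative for decoding", {
  cfg <- scenario_registry("sim1")
  cfg$n_series <- 40
  mnar <- hmm_accuracy_oracle(cfg, channel = "mnar", n_datasets = 8, seed = 2)
  mar <- hmm_accuracy_oracle(cfg, channel = "mar", n_datasets = 8, seed = 2)
  expect_gt(mnar, mar)
  # and the temporal structure beats the static mixture view
  expect_gt(mnar, mixture_accuracy_oracle(cfg, n_points = 50000, seed = 2))
})

test_that("the missingness screen detects attrition and respects the null", {
  cfg <- scenario_registry("sim10")
  hits <- 0
  for (s in 1:10) {
    sim <- simulate_dataset(cfg, seed = 100 + s)
    tab <- missingness_screen(sim$dataset, "time")
    row <- tab[tab$term == "time", ]
    if (row$estimate > 0 && row$lower > 0) hits <- hits + 1
  }
  expect_gte(hits, 9)
  # design-independent missingness: coefficient near zero
  null_cfg <- scenario_registry("sim2")
  zs <- vapply(1:10, function(s) {
    sim <- simulate_dataset(null_cfg, seed = 200 + s)
    tab <- missingness_screen(sim$dataset, "time")
    tab$z[tab$term == "time"]
  }, numeric(1))
  expect_lt(abs(mean(zs)), 1.5)
  expect_true(all(abs(zs) < 4))
  # a dataset with no missing values is refused
  full <- simulate_dataset(scenario_registry("sim2"), seed = 1)
  full$dataset$frame$.y[is.na(full$dataset$frame$.y)] <- 0
  full$dataset <- build_missing_indicator(full$dataset)
  expect_error(missingness_screen(full$dataset, "time"), "degenerate")
})

test_that("the clinical-trial analysis plan counts parameters correctly", {
  plan <- application_config()
  k3 <- plan$specs$K3
  # state+week+main missingness: 6 more free parameters than its restriction
  expect_equal(n_free_parameters(k3$mnar) -
                 n_free_parameters(constrain_mar(k3$mnar)), 6)
  # emission design is intercept-only; drug enters init and transitions
  expect_length(k3$mnar$emission_design, 0)
  expect_equal(k3$mnar$init_design, "drug")
  expect_equal(k3$mnar$transition_design, "drug")
  expect_equal(k3$mnar$missingness_design, c("week", "main"))
  expect_named(plan$specs, paste0("K", 2:5))
})

test_that("a small simulation study is reproducible and complete", {
  cfg <- scenario_registry("sim1")
  cfg$n_series <- 15
  rep1 <- run_simulation_study(cfg, n_datasets = 3, seed = 42)
  rep2 <- run_simulation_study(cfg, n_datasets = 3, seed = 42)
  expect_equal(rep1$parameters, rep2$parameters)
  expect_equal(rep1$recovery, rep2$recovery)
  expect_named(rep1$relative_mae, "mnar_state")
  expect_equal(nrow(rep1$parameters), 18)  # 3 init + 9 trans + 3 means + 3 sds
  expect_true(all(rep1$parameters$mae.mar >= 0))
  expect_true(all(rep1$recovery >= 0 & rep1$recovery <= 100))
  # report exports: JSON round-trips, markdown table has one row per parameter
  jf <- tempfile(fileext = ".json")
  mf <- tempfile(fileext = ".md")
  md <- export_study_report(rep1, json_path = jf, md_path = mf)
  parsed <- jsonlite::fromJSON(jf)
  expect_equal(parsed$n_datasets, 3)
  expect_equal(parsed$relative_mae$mnar_state,
               unname(rep1$relative_mae["mnar_state"]))
  expect_length(readLines(mf), nrow(rep1$parameters) + 2)
})
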