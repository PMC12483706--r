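# Row-wise softmax with a log-sum-exp guard; never returns NaN for finite or
# very large linear predictors.
softmax_rows <- function(eta) {
  eta <- as.matrix(eta)
  m <- apply(eta, 1, max)
  ex <- exp(eta - m)
  ex / rowSums(ex)
}

# Initial state probabilities for every row of a design matrix: n x K.
init_probs_at <- function(X, params) {
  eta <- X %*% t(params$init_coefs)
  softmax_rows(eta)
}

# Transition probabilities for every row of a design matrix: n x K x K array,
# [i, j, k] = P(next = k | current = j) at covariate row i.
transition_probs_at <- function(X, params) {
  K <- params$spec$n_states
  n <- nrow(X)
  out <- array(NA_real_, dim = c(n, K, K))
  for (j in seq_len(K)) {
    eta <- X %*% t(matrix(params$transition_coefs[j, , ], nrow = K))
    out[, j, ] <- softmax_rows(eta)
  }
  out
}

#' Initial state distribution at one covariate row
#'
#' Multinomial-logit (softmax) initial-state probabilities with the reference
#' state's linear predictor fixed at 0.
#'
#' @param covariate_row numeric design row (including the leading intercept 1).
#' @param params an `hmm_params` object.
#' @return A length-K probability vector summing to 1.
#' @export
initial_state_probs <- function(covariate_row, params) {
  stopifnot(inherits(params, "hmm_params"))
  drop(init_probs_at(matrix(covariate_row, nrow = 1), params))
}

#' Transition matrix at one covariate row
#'
#' @inheritParams initial_state_probs
#' @return A K x K stochastic matrix; row j is the distribution of the next
#'   state given current state j.
#' @export
transition_matrix <- function(covariate_row, params) {
  stopifnot(inherits(params, "hmm_params"))
  A <- transition_probs_at(matrix(covariate_row, nrow = 1), params)
  matrix(A[1, , ], nrow = params$spec$n_states)
}

# Per-state missingness probabilities for every row: n x K (MNAR modes only).
missingness_probs_at <- function(X, params) {
  K <- params$spec$n_states
  p <- stats::plogis(X %*% t(params$missingness_coefs))
  if (ncol(p) == 1 && K > 1) p <- p[, rep(1, K), drop = FALSE]  # state_shared
  p
}

#' Observation density contributions for every row and state
#'
#' Combines the Gaussian response density with the Bernoulli mass of the
#' missingness indicator. Under the ignorable (MAR) channel the density of a
#' missing response is exactly 1, so missing occasions carry no observation
#' information while still propagating state probabilities. Under the MNAR
#' channels each row additionally contributes `p_k(x)^m (1 - p_k(x))^(1-m)`,
#' the state-conditional probability of its missingness indicator.
#'
#' @param dataset an `hmm_data` object.
#' @param params an `hmm_params` object.
#' @return A rows x K matrix of strictly positive finite density values.
#' @export
observation_densities <- function(dataset, params) {
  stopifnot(inherits(dataset, "hmm_data"), inherits(params, "hmm_params"))
  spec <- params$spec
  if (any(params$emission_sd <= 0)) stop("emission sd must be > 0", call. = FALSE)
  frame <- dataset$frame
  K <- spec$n_states
  Xobs <- design_matrix(dataset, spec$emission_design)
  mu <- Xobs %*% t(params$emission_coefs)
  dens <- matrix(1, nrow(frame), K)
  obs <- frame$.miss == 0L
  for (k in seq_len(K)) {
    dens[obs, k] <- stats::dnorm(frame$.y[obs], mu[obs, k], params$emission_sd[k])
  }
  if (spec$missingness_mode != "absent") {
    Xmiss <- design_matrix(dataset, spec$missingness_design)
    p <- missingness_probs_at(Xmiss, params)
    m <- frame$.miss
    dens <- dens * (p ^ m) * ((1 - p) ^ (1 - m))
  }
  dens
}

#' Observation density for a single row and state
#'
#' Scalar convenience wrapper around [observation_densities()].
#'
#' @param dataset an `hmm_data` object.
#' @param row row index.
#' @param state state index.
#' @param params an `hmm_params` object.
#' @return A positive real number.
#' @export
observation_density <- function(dataset, row, state, params) {
  observation_densities(dataset, params)[row, state]
}

# Shared setup for the recursions: densities, initial probabilities at the
# first row of each series, and transition arrays at every row (the matrix
# used between t-1 and t is evaluated at the covariates of row t-1).
recursion_inputs <- function(dataset, params) {
  spec <- params$spec
  validate_spec(spec, dataset)
  dens <- observation_densities(dataset, params)
  Xpi <- design_matrix(dataset, spec$init_design, rows = first_rows(dataset))
  pi0 <- init_probs_at(Xpi, params)
  XA <- design_matrix(dataset, spec$transition_design)
  A <- transition_probs_at(XA, params)
  list(dens = dens, pi0 = pi0, A = A)
}

#' Forward-backward smoothing
#'
#' Runs the scaled forward and backward recursions for every series and
#' returns forward/backward variables, smoothed state probabilities
#' (`gamma`), joint transition posteriors (`xi`), and the log-likelihood
#' (the sum of the per-row log normalizers). The recursions are normalized at
#' every step, so arbitrarily long series do not underflow.
#'
#' @param dataset an `hmm_data` object.
#' @param params an `hmm_params` object.
#' @param compute_xi also compute the per-transition joint posteriors
#'   (default `TRUE`).
#' @return An object of class `hmm_posteriors`: list with `forward`,
#'   `backward`, `gamma` (rows x K matrices), `xi` (per series, a
#'   (T-1) x K x K array), `scaling_log` (per-row log normalizer),
#'   `log_likelihood` (total), and `series_loglik`.
#' @export
forward_backward <- function(dataset, params, compute_xi = TRUE) {
  inp <- recursion_inputs(dataset, params)
  starts <- first_rows(dataset)
  lens <- lengths(dataset$series)
  res <- fb_core(inp$dens, inp$pi0, inp$A, as.integer(starts),
                 as.integer(lens), compute_xi)
  series_ll <- as.numeric(res$series_loglik)
  names(series_ll) <- names(dataset$series)
  structure(
    list(forward = res$forward, backward = res$backward, gamma = res$gamma,
         xi = if (compute_xi) res$xi else NULL,
         scaling_log = as.numeric(res$scaling_log),
         log_likelihood = sum(series_ll),
         series_loglik = series_ll),
    class = "hmm_posteriors"
  )
}

#' Log-likelihood of a dataset
#'
#' Sum over series of the scaled forward-recursion log-likelihoods
#' (independent of the backward pass).
#'
#' @inheritParams forward_backward
#' @return Total log-likelihood (a scalar).
#' @export
log_likelihood <- function(dataset, params) {
  inp <- recursion_inputs(dataset, params)
  sum(forward_ll_core(inp$dens, inp$pi0, inp$A,
                      as.integer(first_rows(dataset)),
                      as.integer(lengths(dataset$series))))
}

#' Viterbi decoding of the most probable state paths
#'
#' Computes, for every series, the hidden-state path maximizing the joint
#' probability of states and observations (in log space). States are decoded
#' at missing-response occasions too: the transition structure still makes
#' some states more probable than others there. Ties break toward the lowest
#' state index.
#'
#' @param dataset an `hmm_data` object.
#' @param params an `hmm_params` object.
#' @return A data.frame with columns `id`, `time`, `map_state`, and smoothed
#'   state probabilities `gamma_1` ... `gamma_K`.
#' @export
viterbi_decode <- function(dataset, params) {
  inp <- recursion_inputs(dataset, params)
  K <- params$spec$n_states
  path <- viterbi_core(log(inp$dens), log(inp$pi0), log(inp$A),
                       as.integer(first_rows(dataset)),
                       as.integer(lengths(dataset$series)))
  fb <- forward_backward(dataset, params, compute_xi = FALSE)
  out <- data.frame(id = dataset$frame$.id, time = dataset$frame$.time,
                    map_state = path, stringsAsFactors = FALSE)
  g <- fb$gamma
  colnames(g) <- paste0("gamma_", seq_len(K))
  cbind(out, as.data.frame(g))
}
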