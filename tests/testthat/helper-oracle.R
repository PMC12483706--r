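# Brute-force reference implementations: enumerate all K^T state paths of one
# series and compute the likelihood, smoothed posteriors, and the MAP path by
# direct summation/argmax. Independent of the package's scaled recursions.

oracle_fb <- function(dens, pi0, A_list) {
  Tlen <- nrow(dens)
  K <- ncol(dens)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), Tlen)))
  lp <- log(pi0[paths[, 1]])
  for (t in seq_len(Tlen)) lp <- lp + log(dens[t, ][paths[, t]])
  if (Tlen > 1) {
    for (t in 2:Tlen) {
      lp <- lp + log(A_list[[t - 1]][cbind(paths[, t - 1], paths[, t])])
    }
  }
  p <- exp(lp)
  tot <- sum(p)
  gamma <- matrix(NA_real_, Tlen, K)
  for (t in seq_len(Tlen)) {
    for (k in seq_len(K)) gamma[t, k] <- sum(p[paths[, t] == k]) / tot
  }
  xi <- NULL
  if (Tlen > 1) {
    xi <- array(NA_real_, dim = c(Tlen - 1, K, K))
    for (t in seq_len(Tlen - 1)) {
      for (j in seq_len(K)) for (k in seq_len(K)) {
        xi[t, j, k] <- sum(p[paths[, t] == j & paths[, t + 1] == k]) / tot
      }
    }
  }
  list(loglik = log(tot), gamma = gamma, xi = xi,
       viterbi = as.integer(paths[which.max(lp), ]))
}

# Random one-series test instance: homogeneous intercept-only model with a
# mix of observed and missing responses, under either observation channel.
random_instance <- function(K, Tlen, mode = c("absent", "state_dependent"),
                            seed = 1) {
  mode <- match.arg(mode)
  set.seed(seed)
  y <- stats::rnorm(Tlen)
  miss <- stats::rbinom(Tlen, 1, 0.3)
  y[miss == 1] <- NA
  ds <- long_dataset(data.frame(id = "a", time = seq_len(Tlen), y = y))
  spec <- hmm_spec(K, missingness_mode = mode)
  rdir <- function(n) {
    g <- stats::rgamma(n, 1) + 0.05
    g / sum(g)
  }
  A <- t(vapply(seq_len(K), function(j) rdir(K), numeric(K)))
  params <- params_from_probs(
    spec,
    init_probs = rdir(K),
    transition = A,
    means = stats::rnorm(K),
    sds = stats::runif(K, 0.5, 1.5),
    missingness_probs = if (mode == "absent") NULL else stats::runif(K, 0.1, 0.9)
  )
  list(dataset = ds, params = params, spec = spec)
}

# The recursion inputs the package would use, in oracle-friendly form.
oracle_inputs <- function(inst) {
  dens <- observation_densities(inst$dataset, inst$params)
  pi0 <- initial_state_probs(1, inst$params)
  A <- transition_matrix(1, inst$params)
  Tlen <- nrow(dens)
  list(dens = dens, pi0 = pi0,
       A_list = rep(list(A), max(Tlen - 1, 0)))
}
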