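#' Pseudo-residuals of a fitted model
#'
#' For every observed response, computes the model-implied cumulative
#' probability `u = sum_k w_k * pnorm((y - mu_k)/sigma_k)` and converts it
#' to the corresponding standard-Normal quantile. The normalized weights
#' `w_k` are the posterior state probabilities given *all data except the
#' response being assessed* — forward-predicted probability of the state,
#' times the row's missingness-indicator factor (MNAR channels), times the
#' backward variable. Conditioning out the assessed response is what makes
#' `u` exactly uniform (and the quantiles standard Normal) under a correctly
#' specified model; weights that include it would concentrate `u` around
#' 0.5. Rows with a missing response yield no residual.
#'
#' @param dataset the fitted `hmm_data`.
#' @param fit an `hmm_fit` (or an `hmm_params`).
#' @return A data.frame of class `hmm_pseudo_residuals` with columns `id`,
#'   `time`, `u`, `quantile` (one row per observed response).
#' @export
pseudo_residuals <- function(dataset, fit) {
  params <- if (inherits(fit, "hmm_fit")) fit$params else fit
  stopifnot(inherits(params, "hmm_params"))
  spec <- params$spec
  fb <- forward_backward(dataset, params, compute_xi = FALSE)
  frame <- dataset$frame
  K <- spec$n_states
  n <- nrow(frame)
  # state probabilities given everything but the row's response:
  # predicted forward mass, times the missingness factor, times backward
  inp <- recursion_inputs(dataset, params)
  pred <- matrix(NA_real_, n, K)
  fr <- first_rows(dataset)
  pred[fr, ] <- inp$pi0
  for (s in seq_len(dataset$n_series)) {
    idx <- dataset$series[[s]]
    for (t in seq_along(idx)[-1]) {
      i <- idx[t]
      pred[i, ] <- fb$forward[idx[t - 1], ] %*%
        matrix(inp$A[idx[t - 1], , ], K, K)
    }
  }
  if (spec$missingness_mode != "absent") {
    p <- missingness_probs_at(design_matrix(dataset, spec$missingness_design),
                              params)
    m <- frame$.miss
    pred <- pred * (p ^ m) * ((1 - p) ^ (1 - m))
  }
  w <- pred * fb$backward
  w <- w / rowSums(w)
  obs <- which(frame$.miss == 0L)
  Xobs <- design_matrix(dataset, spec$emission_design, rows = obs)
  mu <- Xobs %*% t(params$emission_coefs)
  P <- matrix(NA_real_, length(obs), K)
  for (k in seq_len(K)) {
    P[, k] <- stats::pnorm((frame$.y[obs] - mu[, k]) / params$emission_sd[k])
  }
  u <- rowSums(w[obs, , drop = FALSE] * P)
  if (any(u <= 1e-12 | u >= 1 - 1e-12)) {
    warning("pseudo-residual probabilities clipped away from 0/1", call. = FALSE)
    u <- pmin(pmax(u, 1e-12), 1 - 1e-12)
  }
  structure(
    data.frame(id = frame$.id[obs], time = frame$.time[obs],
               u = u, quantile = stats::qnorm(u), stringsAsFactors = FALSE),
    class = c("hmm_pseudo_residuals", "data.frame")
  )
}

#' Information criteria of a fit
#'
#' `AIC = -2 logLik + 2 p` and `BIC = -2 logLik + p log(n)` with `p` the
#' free-parameter count and `n` the total number of rows (time points) across
#' series by default; `n_mode = "series"` uses the number of series instead.
#' Reported regardless of convergence (the flag is echoed).
#'
#' @param fit an `hmm_fit`.
#' @param n_mode `"rows"` (default) or `"series"`.
#' @param n_series needed only for `n_mode = "series"`.
#' @return Named list with `AIC`, `BIC`, `log_likelihood`,
#'   `n_free_parameters`, `n`, and `converged`.
#' @export
information_criteria <- function(fit, n_mode = c("rows", "series"), n_series = NULL) {
  stopifnot(inherits(fit, "hmm_fit"))
  n_mode <- match.arg(n_mode)
  p <- fit$n_free_parameters
  n <- if (n_mode == "rows") fit$n_rows else n_series
  ll <- fit$log_likelihood
  list(AIC = -2 * ll + 2 * p,
       BIC = -2 * ll + p * log(n),
       log_likelihood = ll,
       n_free_parameters = p,
       n = n,
       converged = fit$converged)
}

#' Restrict an MNAR specification to its MAR-equivalent
#'
#' Forces the missingness submodel to be identical over the states
#' (`state_shared`), which makes missingness uninformative about the hidden
#' state and yields the null model of the likelihood-ratio test. The
#' free-parameter count drops by `(K - 1) * p_miss`. Idempotent; a K = 1 spec
#' is returned unchanged.
#'
#' @param spec an `hmm_spec` with a missingness channel.
#' @return The restricted `hmm_spec`.
#' @export
constrain_mar <- function(spec) {
  stopifnot(inherits(spec, "hmm_spec"))
  if (spec$missingness_mode == "absent") {
    stop("spec has no missingness channel to restrict", call. = FALSE)
  }
  if (spec$n_states == 1) return(spec)
  spec$missingness_mode <- "state_shared"
  spec
}

#' Likelihood-ratio test of nested fits
#'
#' Tests a restricted model (e.g., the state-shared missingness model from
#' [constrain_mar()]) against the full state-dependent model fitted to the
#' same dataset: `statistic = 2 (logLik_full - logLik_restricted)`, degrees
#' of freedom the difference in free-parameter counts, p-value from the
#' chi-squared distribution.
#'
#' @param restricted,full `hmm_fit` objects; the restricted spec must be
#'   structurally nested in the full one.
#' @return An object of class `hmm_lrt`: list with `statistic`, `df`, and
#'   `p_value`.
#' @export
lr_test <- function(restricted, full) {
  stopifnot(inherits(restricted, "hmm_fit"), inherits(full, "hmm_fit"))
  rs <- restricted$spec
  fs <- full$spec
  nested <- rs$n_states == fs$n_states &&
    identical(rs$init_design, fs$init_design) &&
    identical(rs$transition_design, fs$transition_design) &&
    identical(rs$emission_design, fs$emission_design) &&
    identical(rs$missingness_design, fs$missingness_design) &&
    ((rs$missingness_mode == "state_shared" &&
        fs$missingness_mode == "state_dependent") ||
       identical(rs$missingness_mode, fs$missingness_mode))
  if (!nested) {
    stop("restricted spec is not nested in the full spec", call. = FALSE)
  }
  df <- full$n_free_parameters - restricted$n_free_parameters
  if (df < 0) stop("full model has fewer free parameters than restricted", call. = FALSE)
  stat <- 2 * (full$log_likelihood - restricted$log_likelihood)
  if (stat < -2e-6) {
    warning("likelihood of the full model is below the restricted model ",
            "(statistic ", format(stat), "); consider more EM starts",
            call. = FALSE)
  }
  stat <- max(stat, 0)
  p <- if (df == 0) as.numeric(stat <= 0) else stats::pchisq(stat, df, lower.tail = FALSE)
  structure(list(statistic = stat, df = df, p_value = p), class = "hmm_lrt")
}

#' @export
print.hmm_lrt <- function(x, ...) {
  cat("Likelihood-ratio test: chi-squared =", format(x$statistic, digits = 6),
      ", df =", x$df, ", p =", format.pval(x$p_value, digits = 4), "\n")
  invisible(x)
}

# --- free-parameter packing (used by finite-difference standard errors) ----

pack_params <- function(params) {
  spec <- params$spec
  K <- spec$n_states
  p <- design_sizes(spec)
  out <- numeric(0)
  nm <- character(0)
  dn <- function(design) c("(Intercept)", design)
  if (K > 1) {
    for (k in 2:K) {
      out <- c(out, params$init_coefs[k, ])
      nm <- c(nm, paste0("init.s", k, ".", dn(spec$init_design)))
    }
    for (j in 1:K) for (k in 2:K) {
      out <- c(out, params$transition_coefs[j, k, ])
      nm <- c(nm, paste0("trans.s", j, ".s", k, ".", dn(spec$transition_design)))
    }
  }
  for (k in 1:K) {
    out <- c(out, params$emission_coefs[k, ])
    nm <- c(nm, paste0("emis.s", k, ".", dn(spec$emission_design)))
  }
  out <- c(out, params$emission_sd)
  nm <- c(nm, paste0("sd.s", 1:K))
  if (spec$missingness_mode == "state_dependent") {
    for (k in 1:K) {
      out <- c(out, params$missingness_coefs[k, ])
      nm <- c(nm, paste0("miss.s", k, ".", dn(spec$missingness_design)))
    }
  } else if (spec$missingness_mode == "state_shared") {
    out <- c(out, params$missingness_coefs[1, ])
    nm <- c(nm, paste0("miss.", dn(spec$missingness_design)))
  }
  names(out) <- nm
  out
}

unpack_params <- function(theta, spec) {
  K <- spec$n_states
  p <- design_sizes(spec)
  pos <- 0
  take <- function(n) {
    v <- theta[pos + seq_len(n)]
    pos <<- pos + n
    v
  }
  init_coefs <- matrix(0, K, p[["init"]])
  transition_coefs <- array(0, dim = c(K, K, p[["transition"]]))
  if (K > 1) {
    for (k in 2:K) init_coefs[k, ] <- take(p[["init"]])
    for (j in 1:K) for (k in 2:K) transition_coefs[j, k, ] <- take(p[["transition"]])
  }
  emission_coefs <- matrix(NA_real_, K, p[["emission"]])
  for (k in 1:K) emission_coefs[k, ] <- take(p[["emission"]])
  emission_sd <- take(K)
  missingness_coefs <- NULL
  if (spec$missingness_mode == "state_dependent") {
    missingness_coefs <- matrix(NA_real_, K, p[["missingness"]])
    for (k in 1:K) missingness_coefs[k, ] <- take(p[["missingness"]])
  } else if (spec$missingness_mode == "state_shared") {
    missingness_coefs <- matrix(take(p[["missingness"]]), nrow = 1)
  }
  hmm_params(spec, init_coefs, transition_coefs, emission_coefs,
             emission_sd, missingness_coefs)
}

#' Finite-difference standard errors
#'
#' Estimates the Hessian of the log-likelihood at the fitted parameters by
#' central differences, and returns standard errors as the square roots of
#' the diagonal of the negative inverse Hessian. Parameters whose diagonal
#' entry of the inverse is non-positive (non-positive-definite Hessian) are
#' flagged with `NA` and a warning; a singular Hessian falls back to the
#' Moore-Penrose pseudo-inverse with a warning.
#'
#' @param dataset the fitted `hmm_data`.
#' @param fit an `hmm_fit` at an interior optimum.
#' @param step relative perturbation per parameter (absolute floor `1e-5`).
#' @return A data.frame with columns `parameter`, `estimate`, `se`.
#' @export
fd_standard_errors <- function(dataset, fit, step = 1e-4) {
  stopifnot(inherits(fit, "hmm_fit"))
  spec <- fit$spec
  theta <- pack_params(fit$params)
  npar <- length(theta)
  h <- pmax(abs(theta) * step, 1e-5)
  f <- function(th) log_likelihood(dataset, unpack_params(th, spec))
  H <- matrix(NA_real_, npar, npar)
  f0 <- f(theta)
  for (i in seq_len(npar)) {
    for (j in i:npar) {
      if (i == j) {
        tp <- theta; tp[i] <- theta[i] + h[i]
        tm <- theta; tm[i] <- theta[i] - h[i]
        H[i, i] <- (f(tp) - 2 * f0 + f(tm)) / h[i]^2
      } else {
        tpp <- theta; tpp[i] <- theta[i] + h[i]; tpp[j] <- theta[j] + h[j]
        tpm <- theta; tpm[i] <- theta[i] + h[i]; tpm[j] <- theta[j] - h[j]
        tmp <- theta; tmp[i] <- theta[i] - h[i]; tmp[j] <- theta[j] + h[j]
        tmm <- theta; tmm[i] <- theta[i] - h[i]; tmm[j] <- theta[j] - h[j]
        H[i, j] <- H[j, i] <- (f(tpp) - f(tpm) - f(tmp) + f(tmm)) / (4 * h[i] * h[j])
      }
    }
  }
  Vn <- tryCatch(solve(-H), error = function(e) {
    warning("singular Hessian: using pseudo-inverse", call. = FALSE)
    MASS::ginv(-H)
  })
  d <- diag(Vn)
  se <- rep(NA_real_, npar)
  ok <- is.finite(d) & d > 0
  se[ok] <- sqrt(d[ok])
  if (any(!ok)) {
    warning("non-positive-definite Hessian for parameter(s): ",
            paste(names(theta)[!ok], collapse = ", "), call. = FALSE)
  }
  data.frame(parameter = names(theta), estimate = as.numeric(theta), se = se,
             stringsAsFactors = FALSE)
}
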