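# Separation guard shared by the logistic/multinomial M-steps: probabilities
# are clipped away from 0/1 and coefficients capped, since early EM iterations
# can put (numerically) zero weight on a category.
PROB_CLIP <- 1e-10
COEF_CAP <- 15

clip_prob <- function(p) pmin(pmax(p, PROB_CLIP), 1 - PROB_CLIP)

separation_warning <- function(...) {
  warning(warningCondition(paste0(...), class = "mnarhmm_separation"))
}

cap_coefs <- function(b, context = "fit") {
  if (any(abs(b) > COEF_CAP, na.rm = TRUE)) {
    separation_warning("separation-like estimates in ", context,
                       ": coefficients capped at |", COEF_CAP, "|")
    b <- pmin(pmax(b, -COEF_CAP), COEF_CAP)
  }
  b
}

#' Weighted Gaussian regression fit
#'
#' Weighted least squares with the maximum-likelihood variance estimate:
#' coefficients minimize the weighted squared error and
#' `sigma = sqrt(weighted SSR / sum(weights))`.
#'
#' @param y observed responses (no missing values).
#' @param weights nonnegative case weights with positive sum.
#' @param X design matrix (first column usually an intercept).
#' @return List with `coefficients` and `sigma`.
#' @export
weighted_gaussian_fit <- function(y, weights, X) {
  X <- as.matrix(X)
  sw <- sum(weights)
  if (!is.finite(sw) || sw <= 0) {
    stop("degenerate state: weights sum to zero in Gaussian M-step", call. = FALSE)
  }
  fit <- stats::lm.wfit(X, y, w = weights)
  if (fit$rank < ncol(X)) {
    dropped <- colnames(X)[is.na(fit$coefficients)]
    stop("rank-deficient emission design; collinear column(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  sigma <- sqrt(sum(weights * fit$residuals^2) / sw)
  list(coefficients = fit$coefficients, sigma = sigma)
}

#' Weighted logistic regression fit
#'
#' Maximizes the weighted Bernoulli log-likelihood by IRLS. Intercept-only
#' designs use the closed form (logit of the weighted mean). Fitted
#' probabilities are clipped away from 0 and 1 and coefficients capped (see
#' package vignette) as a fallback under complete separation.
#'
#' @param m binary outcomes (0/1).
#' @param weights nonnegative case weights with positive sum.
#' @param X design matrix.
#' @return Named coefficient vector with attribute `"vcov"`, the inverse
#'   Fisher information at the estimate.
#' @export
weighted_logistic_fit <- function(m, weights, X) {
  X <- as.matrix(X)
  sw <- sum(weights)
  if (!is.finite(sw) || sw <= 0) {
    stop("degenerate state: weights sum to zero in logistic M-step", call. = FALSE)
  }
  if (ncol(X) == 1 && all(X[, 1] == 1)) {
    p <- clip_prob(sum(weights * m) / sw)
    b <- cap_coefs(stats::qlogis(p), "logistic M-step")
    names(b) <- colnames(X)
    attr(b, "vcov") <- matrix(1 / (sw * p * (1 - p)), 1, 1,
                              dimnames = list(colnames(X), colnames(X)))
    return(b)
  }
  fit <- suppressWarnings(stats::glm.fit(
    X, m, weights = weights, family = stats::quasibinomial(),
    control = stats::glm.control(epsilon = 1e-12, maxit = 100)
  ))
  b <- cap_coefs(fit$coefficients, "logistic M-step")
  names(b) <- colnames(X)
  pfit <- clip_prob(stats::plogis(drop(X %*% b)))
  info <- crossprod(X, X * (weights * pfit * (1 - pfit)))
  v <- tryCatch(solve(info), error = function(e) MASS::ginv(info))
  dimnames(v) <- list(colnames(X), colnames(X))
  attr(b, "vcov") <- v
  b
}

# Core multinomial M-step taking a rows x K matrix of nonnegative category
# weights (posterior probabilities) and a design matrix. Returns a K x p
# coefficient matrix with the reference (category 1) row fixed at 0.
mstep_multinomial <- function(Y, X) {
  Y <- as.matrix(Y)
  X <- as.matrix(X)
  K <- ncol(Y)
  p <- ncol(X)
  if (sum(Y) <= 0) {
    stop("degenerate state: weights sum to zero in multinomial M-step", call. = FALSE)
  }
  if (K == 1) return(matrix(0, 1, p))
  if (p == 1 && all(X[, 1] == 1)) {
    wk <- colSums(Y)
    if (any(wk <= 0)) {
      separation_warning("category with zero weight in multinomial M-step; ",
                         "probabilities clipped")
    }
    pr <- clip_prob(wk / sum(wk))
    b <- cap_coefs(log(pr) - log(pr[1]), "multinomial M-step")
    return(matrix(b, K, 1))
  }
  fit <- nnet::multinom(Y ~ 0 + X, trace = FALSE, maxit = 500,
                        reltol = 1e-12, MaxNWts = 5000)
  cf <- stats::coef(fit)
  if (is.null(dim(cf))) cf <- matrix(cf, nrow = 1)
  cf <- cap_coefs(cf, "multinomial M-step")
  rbind(matrix(0, 1, p), cf)
}

#' Weighted multinomial logistic regression fit
#'
#' Maximizes the weighted multinomial log-likelihood; the reference category
#' (category 1) has its coefficients fixed at 0. With `n_categories = 2` this
#' reduces to [weighted_logistic_fit()] of the indicator of category 2.
#'
#' @param categories integer outcomes in `1..n_categories`.
#' @param weights nonnegative case weights with positive sum.
#' @param X design matrix.
#' @param n_categories number of categories K (default: max observed).
#' @return A K x p coefficient matrix (row 1 zero); a 1 x p zero matrix when
#'   K = 1.
#' @export
weighted_multinomial_fit <- function(categories, weights, X,
                                     n_categories = max(categories)) {
  X <- as.matrix(X)
  K <- as.integer(n_categories)
  Y <- matrix(0, length(categories), K)
  Y[cbind(seq_along(categories), categories)] <- weights
  mstep_multinomial(Y, X)
}

#' EM iteration controls
#'
#' @param max_iterations maximum number of EM iterations.
#' @param tolerance absolute log-likelihood change below which the algorithm
#'   is declared converged; must be > 0.
#' @param n_starts number of random starts for [multistart_fit()].
#' @param seed integer seed governing random starts.
#' @return An object of class `em_controls`.
#' @export
em_controls <- function(max_iterations = 500, tolerance = 1e-6,
                        n_starts = 10, seed = 1) {
  if (!is.numeric(tolerance) || tolerance <= 0) stop("tolerance must be > 0", call. = FALSE)
  if (max_iterations < 1) stop("max_iterations must be >= 1", call. = FALSE)
  structure(list(max_iterations = as.integer(max_iterations),
                 tolerance = tolerance,
                 n_starts = as.integer(n_starts),
                 seed = seed),
            class = "em_controls")
}

#' One EM (Baum-Welch) step
#'
#' E-step: forward-backward smoothing under the current parameters. M-step:
#' four separate weighted maximum-likelihood fits — the initial-state
#' multinomial logit on the first occasions with gamma weights; the
#' transition multinomial logit per origin state on "from"-occasion design
#' rows with xi weights; the Gaussian emission model per state on
#' observed-response rows with gamma weights; and the logistic missingness
#' model per state on all rows with gamma weights (pooled across states in
#' `state_shared` mode, skipped under MAR).
#'
#' @param dataset an `hmm_data` object.
#' @param params current `hmm_params`.
#' @return List with `params` (updated) and `loglik`, the log-likelihood of
#'   the *incoming* parameters.
#' @export
em_step <- function(dataset, params) {
  spec <- params$spec
  K <- spec$n_states
  fb <- forward_backward(dataset, params)
  frame <- dataset$frame

  gsum <- colSums(fb$gamma)
  if (any(gsum < 1e-8)) {
    stop("degenerate state (posterior mass ~ 0 for state ",
         which.min(gsum), "); re-initialize with different start values",
         call. = FALSE)
  }

  # initial-state submodel: t = 1 rows, gamma weights
  fr <- first_rows(dataset)
  Xpi <- design_matrix(dataset, spec$init_design, rows = fr)
  init_coefs <- mstep_multinomial(fb$gamma[fr, , drop = FALSE], Xpi)

  # transition submodel: "from" occasions, xi weights, per origin state
  from_rows <- unlist(lapply(dataset$series, function(idx) idx[-length(idx)]),
                      use.names = FALSE)
  p_A <- design_sizes(spec)[["transition"]]
  transition_coefs <- array(0, dim = c(K, K, p_A))
  if (length(from_rows) > 0) {
    XA <- design_matrix(dataset, spec$transition_design, rows = from_rows)
    for (j in seq_len(K)) {
      Yj <- do.call(rbind, lapply(fb$xi, function(x) {
        if (dim(x)[1] == 0) matrix(0, 0, K) else matrix(x[, j, ], ncol = K)
      }))
      transition_coefs[j, , ] <- mstep_multinomial(Yj, XA)
    }
  }

  # emission submodel: observed-response rows only, gamma weights
  obs <- which(frame$.miss == 0L)
  Xobs <- design_matrix(dataset, spec$emission_design, rows = obs)
  p_obs <- design_sizes(spec)[["emission"]]
  emission_coefs <- matrix(NA_real_, K, p_obs)
  emission_sd <- numeric(K)
  for (k in seq_len(K)) {
    gf <- weighted_gaussian_fit(frame$.y[obs], fb$gamma[obs, k], Xobs)
    emission_coefs[k, ] <- gf$coefficients
    emission_sd[k] <- max(gf$sigma, 1e-6)
  }

  # missingness submodel
  missingness_coefs <- NULL
  if (spec$missingness_mode != "absent") {
    Xmiss <- design_matrix(dataset, spec$missingness_design)
    if (spec$missingness_mode == "state_dependent") {
      p_m <- design_sizes(spec)[["missingness"]]
      missingness_coefs <- matrix(NA_real_, K, p_m)
      for (k in seq_len(K)) {
        missingness_coefs[k, ] <- weighted_logistic_fit(frame$.miss,
                                                        fb$gamma[, k], Xmiss)
      }
    } else {
      # state_shared: gamma weights sum to 1 within each row, so pooling the
      # K weighted copies collapses to a unit-weight fit.
      missingness_coefs <- matrix(
        weighted_logistic_fit(frame$.miss, rep(1, nrow(frame)), Xmiss),
        nrow = 1
      )
    }
  }

  new_params <- hmm_params(spec,
                           init_coefs = init_coefs,
                           transition_coefs = transition_coefs,
                           emission_coefs = emission_coefs,
                           emission_sd = emission_sd,
                           missingness_coefs = missingness_coefs)
  list(params = new_params, loglik = fb$log_likelihood)
}

#' Fit by EM (Baum-Welch) from given start values
#'
#' Iterates [em_step()] until the absolute log-likelihood change drops below
#' `controls$tolerance` or `controls$max_iterations` is reached.
#' Non-convergence is reported via the `converged` flag, not an error.
#'
#' @param dataset an `hmm_data` object.
#' @param spec an `hmm_spec`.
#' @param start an `hmm_params` start value consistent with `spec`.
#' @param controls an [em_controls()] object.
#' @param seed optional integer recorded in the result (the deterministic EM
#'   itself uses no randomness).
#' @return An object of class `hmm_fit`: list with `params`,
#'   `log_likelihood`, `n_iterations`, `converged`, `n_free_parameters`,
#'   `trace` (per-iteration log-likelihood, non-decreasing), `spec`, `seed`,
#'   `n_rows`, and `n_obs_rows`.
#' @export
em_fit <- function(dataset, spec, start, controls = em_controls(), seed = NULL) {
  stopifnot(inherits(spec, "hmm_spec"), inherits(start, "hmm_params"))
  validate_spec(spec, dataset)
  params <- start
  trace <- numeric(0)
  converged <- FALSE
  it <- 0L
  n_separation <- 0L
  # separation warnings inside the loop are counted, not repeated per iteration
  withCallingHandlers(
    repeat {
      it <- it + 1L
      st <- em_step(dataset, params)
      trace[it] <- st$loglik
      if (it > 1 && abs(trace[it] - trace[it - 1]) < controls$tolerance) {
        converged <- TRUE
        break
      }
      if (it >= controls$max_iterations) break
      params <- st$params
    },
    mnarhmm_separation = function(w) {
      n_separation <<- n_separation + 1L
      invokeRestart("muffleWarning")
    }
  )
  if (n_separation > 0) {
    separation_warning("separation fallback triggered in ", n_separation,
                       " M-step fit(s) during EM")
  }
  structure(
    list(params = params,
         log_likelihood = trace[it],
         n_iterations = it,
         converged = converged,
         n_free_parameters = n_free_parameters(spec),
         trace = trace,
         spec = spec,
         seed = seed,
         n_rows = nrow(dataset$frame),
         n_obs_rows = sum(dataset$frame$.miss == 0L),
         n_separation_warnings = n_separation),
    class = "hmm_fit"
  )
}

#' @export
print.hmm_fit <- function(x, ...) {
  cat("HMM fit: K =", x$spec$n_states, "| missingness:", x$spec$missingness_mode,
      "\n  logLik =", format(x$log_likelihood, digits = 8),
      "| iterations =", x$n_iterations,
      "| converged =", x$converged,
      "| free parameters =", x$n_free_parameters, "\n")
  invisible(x)
}

#' Random EM start values
#'
#' Initial and transition probabilities are sampled from flat Dirichlet(1)
#' distributions and converted to multinomial-logit intercepts (covariate
#' slopes start at 0). Emission and missingness parameters are then set by
#' weighted fits against per-row state probabilities sampled from a flat
#' Dirichlet, so that start values respect the scale of the data.
#'
#' @param dataset an `hmm_data` object.
#' @param spec an `hmm_spec`.
#' @param seed integer seed; the same seed yields identical start values.
#' @return An `hmm_params` object.
#' @export
generate_start_values <- function(dataset, spec, seed = NULL) {
  validate_spec(spec, dataset)
  if (!is.null(seed)) set.seed(seed)
  K <- spec$n_states
  p <- design_sizes(spec)
  frame <- dataset$frame
  rdirichlet1 <- function(n) {
    g <- matrix(stats::rgamma(n * K, shape = 1), n, K)
    g / rowSums(g)
  }
  init_coefs <- matrix(0, K, p[["init"]])
  init_coefs[, 1] <- probs_to_logits(drop(rdirichlet1(1)))
  transition_coefs <- array(0, dim = c(K, K, p[["transition"]]))
  for (j in seq_len(K)) transition_coefs[j, , 1] <- probs_to_logits(drop(rdirichlet1(1)))
  W <- rdirichlet1(nrow(frame))
  obs <- which(frame$.miss == 0L)
  Xobs <- design_matrix(dataset, spec$emission_design, rows = obs)
  emission_coefs <- matrix(NA_real_, K, p[["emission"]])
  emission_sd <- numeric(K)
  for (k in seq_len(K)) {
    gf <- weighted_gaussian_fit(frame$.y[obs], W[obs, k], Xobs)
    emission_coefs[k, ] <- gf$coefficients
    emission_sd[k] <- max(gf$sigma, 1e-3)
  }
  missingness_coefs <- NULL
  if (spec$missingness_mode == "state_dependent") {
    Xmiss <- design_matrix(dataset, spec$missingness_design)
    missingness_coefs <- matrix(NA_real_, K, p[["missingness"]])
    for (k in seq_len(K)) {
      missingness_coefs[k, ] <- as.numeric(
        weighted_logistic_fit(frame$.miss, W[, k], Xmiss))
    }
  } else if (spec$missingness_mode == "state_shared") {
    Xmiss <- design_matrix(dataset, spec$missingness_design)
    missingness_coefs <- matrix(
      weighted_logistic_fit(frame$.miss, rep(1, nrow(frame)), Xmiss), nrow = 1)
  }
  hmm_params(spec, init_coefs, transition_coefs, emission_coefs,
             emission_sd, missingness_coefs)
}

#' Multistart EM fit
#'
#' Runs [em_fit()] from `controls$n_starts` random starts (seeds derived
#' deterministically from `controls$seed`) and returns the fit with the best
#' log-likelihood. Per-start final log-likelihoods are attached as
#' `start_logliks`.
#'
#' @inheritParams em_fit
#' @return The best `hmm_fit`, with elements `start_logliks` and
#'   `start_seeds` added.
#' @export
multistart_fit <- function(dataset, spec, controls = em_controls()) {
  stopifnot(controls$n_starts >= 1)
  set.seed(controls$seed)
  seeds <- sample.int(.Machine$integer.max %/% 2, controls$n_starts)
  fits <- vector("list", controls$n_starts)
  lls <- rep(NA_real_, controls$n_starts)
  errs <- character(0)
  for (i in seq_len(controls$n_starts)) {
    res <- tryCatch({
      start <- generate_start_values(dataset, spec, seed = seeds[i])
      em_fit(dataset, spec, start, controls, seed = seeds[i])
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errs <- c(errs, conditionMessage(res))
    } else {
      fits[[i]] <- res
      lls[i] <- res$log_likelihood
    }
  }
  if (all(is.na(lls))) {
    stop("all ", controls$n_starts, " EM starts failed: ",
         paste(unique(errs), collapse = " | "), call. = FALSE)
  }
  best <- fits[[which.max(lls)]]
  best$start_logliks <- lls
  best$start_seeds <- seeds
  best
}

#' Serialize a fit to JSON
#'
#' @param fit an `hmm_fit`.
#' @param path optional output path; when `NULL` the JSON string is returned.
#' @return The JSON string (invisibly when written to a file).
#' @export
fit_to_json <- function(fit, path = NULL) {
  stopifnot(inherits(fit, "hmm_fit"))
  obj <- list(
    spec = unclass(fit$spec),
    coefficients = list(
      init = fit$params$init_coefs,
      transition = fit$params$transition_coefs,
      emission = fit$params$emission_coefs,
      emission_sd = fit$params$emission_sd,
      missingness = fit$params$missingness_coefs
    ),
    log_likelihood = fit$log_likelihood,
    n_iterations = fit$n_iterations,
    converged = fit$converged,
    n_free_parameters = fit$n_free_parameters,
    trace = fit$trace,
    seed = fit$seed
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
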