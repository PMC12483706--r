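#' Specify a hidden Markov model with an optional missingness channel
#'
#' Defines the structure of the model: number of hidden states, the covariate
#' design of each regression submodel (each implicitly containing an
#' intercept), the Gaussian emission family, and the missingness channel.
#'
#' Missingness modes:
#' * `"absent"` — ignorable (MAR) model: the missingness indicator does not
#'   enter the likelihood.
#' * `"state_shared"` — restricted MNAR model: a single logistic missingness
#'   submodel shared by all states (the MAR-equivalent restriction used as the
#'   null of the likelihood-ratio test).
#' * `"state_dependent"` — full MNAR model: one logistic missingness submodel
#'   per hidden state.
#'
#' @param n_states number of hidden states K (>= 1).
#' @param init_design covariate names for the multinomial-logit initial-state
#'   submodel.
#' @param transition_design covariate names for the multinomial-logit
#'   transition submodel.
#' @param emission_design covariate names for the Gaussian mean submodel.
#' @param missingness_design covariate names for the logistic missingness
#'   submodel.
#' @param missingness_mode one of `"absent"`, `"state_shared"`,
#'   `"state_dependent"`.
#' @return An object of class `hmm_spec`.
#' @export
hmm_spec <- function(n_states,
                     init_design = character(),
                     transition_design = character(),
                     emission_design = character(),
                     missingness_design = character(),
                     missingness_mode = c("absent", "state_shared", "state_dependent")) {
  missingness_mode <- match.arg(missingness_mode)
  n_states <- as.integer(n_states)
  if (is.na(n_states) || n_states < 1) stop("n_states must be >= 1", call. = FALSE)
  structure(
    list(n_states = n_states,
         init_design = as.character(init_design),
         transition_design = as.character(transition_design),
         emission_design = as.character(emission_design),
         missingness_design = as.character(missingness_design),
         missingness_mode = missingness_mode),
    class = "hmm_spec"
  )
}

#' @export
print.hmm_spec <- function(x, ...) {
  cat("HMM specification: K =", x$n_states,
      "| missingness:", x$missingness_mode, "\n")
  des <- function(d) if (length(d) == 0) "1" else paste(c("1", d), collapse = " + ")
  cat("  init ~", des(x$init_design), "| transition ~", des(x$transition_design),
      "\n  emission ~", des(x$emission_design))
  if (x$missingness_mode != "absent") cat(" | missingness ~", des(x$missingness_design))
  cat("\n")
  invisible(x)
}

# Number of columns (incl. intercept) of each submodel design.
design_sizes <- function(spec) {
  c(init = length(spec$init_design) + 1L,
    transition = length(spec$transition_design) + 1L,
    emission = length(spec$emission_design) + 1L,
    missingness = if (spec$missingness_mode == "absent") 0L
                  else length(spec$missingness_design) + 1L)
}

#' Count free parameters of a specification
#'
#' Counts non-reference, non-fixed coefficients plus the K emission standard
#' deviations. Reference-state (state 1) multinomial-logit coefficients are
#' fixed at 0 for identification and do not count.
#'
#' @param spec an `hmm_spec`.
#' @return Integer free-parameter count.
#' @export
n_free_parameters <- function(spec) {
  stopifnot(inherits(spec, "hmm_spec"))
  K <- spec$n_states
  p <- design_sizes(spec)
  n_miss <- switch(spec$missingness_mode,
                   absent = 0L,
                   state_shared = p[["missingness"]],
                   state_dependent = K * p[["missingness"]])
  as.integer((K - 1L) * p[["init"]] +     # initial-state multinomial logit
             K * (K - 1L) * p[["transition"]] +
             K * p[["emission"]] + K +    # emission coefficients + K sigmas
             n_miss)
}

#' Bundle model parameters
#'
#' Collects the coefficients of the four submodels. Multinomial-logit
#' coefficient blocks carry a row/slice for every state with the reference
#' state (state 1) fixed at zero.
#'
#' @param spec an `hmm_spec`.
#' @param init_coefs K x p_init matrix; row 1 must be zero.
#' @param transition_coefs K x K x p_trans array; `transition_coefs[j, k, ]`
#'   are the logit coefficients of moving from state j to state k;
#'   `transition_coefs[, 1, ]` must be zero.
#' @param emission_coefs K x p_obs matrix of Gaussian mean coefficients.
#' @param emission_sd length-K vector of positive standard deviations.
#' @param missingness_coefs logistic coefficients: K x p_miss matrix
#'   (`state_dependent`), 1 x p_miss (`state_shared`), or `NULL` (`absent`).
#' @return An object of class `hmm_params`.
#' @export
hmm_params <- function(spec, init_coefs, transition_coefs, emission_coefs,
                       emission_sd, missingness_coefs = NULL) {
  stopifnot(inherits(spec, "hmm_spec"))
  K <- spec$n_states
  p <- design_sizes(spec)
  init_coefs <- as.matrix(init_coefs)
  if (!all(dim(init_coefs) == c(K, p[["init"]]))) {
    stop("init_coefs must be ", K, " x ", p[["init"]], call. = FALSE)
  }
  if (any(abs(init_coefs[1, ]) > 0)) {
    stop("reference-state (state 1) init coefficients must be 0", call. = FALSE)
  }
  transition_coefs <- array(transition_coefs, dim = c(K, K, p[["transition"]]))
  if (any(abs(transition_coefs[, 1, ]) > 0)) {
    stop("reference-state (column 1) transition coefficients must be 0", call. = FALSE)
  }
  emission_coefs <- as.matrix(emission_coefs)
  if (!all(dim(emission_coefs) == c(K, p[["emission"]]))) {
    stop("emission_coefs must be ", K, " x ", p[["emission"]], call. = FALSE)
  }
  emission_sd <- as.numeric(emission_sd)
  if (length(emission_sd) != K || any(!is.finite(emission_sd)) || any(emission_sd <= 0)) {
    stop("emission_sd must be ", K, " positive values", call. = FALSE)
  }
  if (spec$missingness_mode == "absent") {
    missingness_coefs <- NULL
  } else {
    if (is.null(missingness_coefs)) {
      stop("missingness_coefs required for mode ", spec$missingness_mode, call. = FALSE)
    }
    missingness_coefs <- as.matrix(missingness_coefs)
    want_rows <- if (spec$missingness_mode == "state_shared") 1L else K
    if (!all(dim(missingness_coefs) == c(want_rows, p[["missingness"]]))) {
      stop("missingness_coefs must be ", want_rows, " x ", p[["missingness"]],
           call. = FALSE)
    }
  }
  structure(
    list(init_coefs = init_coefs,
         transition_coefs = transition_coefs,
         emission_coefs = emission_coefs,
         emission_sd = emission_sd,
         missingness_coefs = missingness_coefs,
         spec = spec),
    class = "hmm_params"
  )
}

#' @export
print.hmm_params <- function(x, ...) {
  K <- x$spec$n_states
  cat("HMM parameters (K =", K, ", missingness:", x$spec$missingness_mode, ")\n")
  cat("  emission means (at zero covariates):",
      paste(signif(x$emission_coefs[, 1], 4), collapse = ", "), "\n")
  cat("  emission sd:", paste(signif(x$emission_sd, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Build parameters from probabilities (intercept-only submodels)
#'
#' Convenience constructor for homogeneous, covariate-free models: converts
#' probabilities to the equivalent multinomial/logistic intercepts (reference
#' state 1).
#'
#' @param spec an `hmm_spec` whose designs are all empty (intercept-only).
#' @param init_probs length-K initial state distribution.
#' @param transition K x K transition matrix (rows sum to 1).
#' @param means length-K state-conditional means.
#' @param sds length-K state-conditional standard deviations.
#' @param missingness_probs per-state missingness probabilities (length K), a
#'   single shared probability (`state_shared`), or `NULL`.
#' @return An `hmm_params` object.
#' @export
params_from_probs <- function(spec, init_probs, transition, means, sds,
                              missingness_probs = NULL) {
  stopifnot(inherits(spec, "hmm_spec"))
  if (any(design_sizes(spec)[c("init", "transition", "emission")] != 1L)) {
    stop("params_from_probs requires intercept-only init/transition/emission designs",
         call. = FALSE)
  }
  K <- spec$n_states
  init_coefs <- matrix(probs_to_logits(init_probs), ncol = 1)
  transition <- as.matrix(transition)
  tc <- array(0, dim = c(K, K, 1))
  for (j in seq_len(K)) tc[j, , 1] <- probs_to_logits(transition[j, ])
  mc <- NULL
  if (spec$missingness_mode == "state_dependent") {
    mc <- matrix(stats::qlogis(missingness_probs), ncol = 1)
  } else if (spec$missingness_mode == "state_shared") {
    mc <- matrix(stats::qlogis(missingness_probs[1]), ncol = 1)
  }
  hmm_params(spec,
             init_coefs = init_coefs,
             transition_coefs = tc,
             emission_coefs = matrix(means, ncol = 1),
             emission_sd = sds,
             missingness_coefs = mc)
}

# log-odds against reference category 1; probabilities clipped away from 0.
probs_to_logits <- function(p) {
  p <- pmin(pmax(p, 1e-12), 1)
  log(p) - log(p[1])
}

# Validate that a spec's covariate names exist in the dataset.
validate_spec <- function(spec, dataset) {
  stopifnot(inherits(spec, "hmm_spec"), inherits(dataset, "hmm_data"))
  all_cov <- unique(c(spec$init_design, spec$transition_design,
                      spec$emission_design, spec$missingness_design))
  unknown <- setdiff(all_cov, names(dataset$frame))
  if (length(unknown) > 0) {
    stop("spec names covariate(s) absent from the dataset: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}
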