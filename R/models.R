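#' @useDynLib discountDDM, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Model registry: parameter layout and support bounds
#'
#' Column order of the subject-level parameter matrix for each model, and the
#' support of every parameter. The supports double as the bounds of the
#' uniform priors on the group-level means and as the truncation limits of
#' the subject-level Gaussians.
#'
#' @param model One of `"softmax"`, `"ddm0"`, `"ddml"`, `"ddms"`.
#' @return Character vector of parameter names (`model_params`) or a 2-row
#'   matrix of lower/upper bounds with one column per parameter
#'   (`param_bounds`).
#' @export
model_params <- function(model) {
  switch(match.arg(model, c("softmax", "ddm0", "ddml", "ddms")),
    softmax = c("log_k", "beta"),
    ddm0    = c("v", "alpha", "tau", "z"),
    ddml    = c("log_k", "v_coeff", "alpha", "tau", "z"),
    ddms    = c("log_k", "v_coeff", "v_max", "alpha", "tau", "z")
  )
}

.PARAM_BOUNDS <- rbind(
  lower = c(log_k = -20, beta = 0, v = -100, tau = 0.1, alpha = 0.01,
            z = 0.1, v_coeff = -100, v_max = 0),
  upper = c(log_k = 3, beta = 10, v = 100, tau = 6, alpha = 5,
            z = 0.9, v_coeff = 100, v_max = 100)
)

#' @rdname model_params
#' @export
param_bounds <- function(model) {
  .PARAM_BOUNDS[, model_params(model), drop = FALSE]
}

.MODEL_CODE <- c(softmax = 1L, ddm0 = 2L, ddml = 3L, ddms = 4L)

#' Hyperbolic subjective value of a delayed reward
#'
#' SV = amount / (1 + exp(log_k) * delay). The discount rate k is carried in
#' log-space throughout the package; higher log_k means steeper devaluation.
#'
#' @param amount Reward magnitude (Euros), > 0.
#' @param delay Delay in days, >= 0.
#' @param log_k Log discount rate.
#' @return Discounted value, same units as `amount`.
#' @export
subjective_value <- function(amount, delay, log_k) {
  stopifnot(all(amount > 0), all(delay >= 0))
  amount / (1 + exp(log_k) * delay)
}

#' Softmax probability of choosing the larger-later option
#'
#' P(LL) = exp(sv_ll * beta) / (exp(sv_ss * beta) + exp(sv_ll * beta)),
#' computed overflow-safely. beta = 0 gives random choice (0.5).
#'
#' @param sv_ss,sv_ll Subjective values of the two options.
#' @param beta Inverse temperature, >= 0.
#' @return Probability in (0, 1).
#' @export
softmax_p_ll <- function(sv_ss, sv_ll, beta) {
  stopifnot(all(beta >= 0))
  stats::plogis(beta * (sv_ll - sv_ss))
}

#' Trial-wise drift rate under the three value-to-drift mappings
#'
#' `constant` ignores the values and returns `v`; `linear` returns
#' v_coeff * (sv_ll - sv_ss); `sigmoid` passes the linear term m through
#' S(m) = 2 * v_max / (1 + exp(-m)) - v_max, bounding drift in
#' (-v_max, v_max).
#'
#' @param sv_ss,sv_ll Subjective values.
#' @param mapping `"constant"`, `"linear"` or `"sigmoid"`.
#' @param params Named list/vector with the fields the mapping needs
#'   (`v`, `v_coeff`, `v_max`).
#' @return Drift rate(s).
#' @export
drift_rate <- function(sv_ss, sv_ll, mapping = c("constant", "linear", "sigmoid"),
                       params) {
  mapping <- match.arg(mapping)
  p <- as.list(params)
  if (mapping == "constant") {
    if (is.null(p$v)) stop("constant mapping requires 'v'")
    return(rep_len(p$v, max(length(sv_ss), length(sv_ll))))
  }
  if (is.null(p$v_coeff)) stop(mapping, " mapping requires 'v_coeff'")
  m <- p$v_coeff * (sv_ll - sv_ss)
  if (mapping == "linear") return(m)
  if (is.null(p$v_max)) stop("sigmoid mapping requires 'v_max'")
  2 * p$v_max / (1 + exp(-m)) - p$v_max
}

#' Wiener first-passage-time log density for signed response times
#'
#' Density of a unit-diffusion Wiener process with boundary separation
#' `alpha`, non-decision time `tau`, relative starting point `z` and drift
#' `v`, first hitting the boundary indicated by the sign of `rt` at time
#' `|rt|`. Positive sign = upper boundary (larger-later choice). The
#' upper-boundary density is obtained from the lower-boundary kernel by the
#' reflection v -> -v, z -> 1 - z. Small-time and large-time series
#' expansions are selected per evaluation to meet the absolute tolerance
#' `err`. `|rt| <= tau` yields `-Inf` (no decision before the non-decision
#' time).
#'
#' @param rt Signed response times (seconds).
#' @param v Drift rate, scalar or one value per rt.
#' @param alpha Boundary separation, > 0.
#' @param tau Non-decision time (s), > 0.
#' @param z Relative starting point in (0, 1).
#' @param err Absolute series-truncation tolerance.
#' @return Log densities, same length as `rt`.
#' @export
wfpt_logdensity <- function(rt, v, alpha, tau, z, err = 1e-9) {
  if (!all(is.finite(c(v, alpha, tau, z))) || alpha <= 0 || tau <= 0 ||
      z <= 0 || z >= 1)
    stop("non-finite or out-of-range wfpt parameters")
  wfpt_logdensity_cpp(as.numeric(rt), as.numeric(v), alpha, tau, z, err)
}

#' Total log-likelihood of one prepared session under a model
#'
#' Sums log choice probabilities (softmax) or wfpt log densities (DDM
#' variants) over the retained trials of one subject-session, with
#' subjective values from the hyperbolic rule feeding both. Trials with
#' `|rt| <= tau` under a DDM model contribute `-Inf`.
#'
#' @param model One of `"softmax"`, `"ddm0"`, `"ddml"`, `"ddms"`.
#' @param params Named vector/list of the model's parameters
#'   (see [model_params()]).
#' @param prepared A `prepared_session` from [preprocess_rts()], or any data
#'   frame with signed `rt`, `ll_amount`, `delay_days` columns.
#' @param err wfpt tolerance.
#' @return Scalar log-likelihood.
#' @export
session_loglik <- function(model, params, prepared, err = 1e-9) {
  model <- match.arg(model, names(.MODEL_CODE))
  rec <- if (inherits(prepared, "prepared_session")) prepared$records else prepared
  pn <- model_params(model)
  p <- unlist(params)[pn]
  if (anyNA(p)) stop("params must supply: ", paste(pn, collapse = ", "))
  ss <- if ("ss_amount" %in% names(rec)) rec$ss_amount[1] else 20
  loglik_subjects_cpp(.MODEL_CODE[[model]],
                      rep(0L, nrow(rec)),
                      as.numeric(rec$rt),
                      as.numeric(rec$ll_amount),
                      as.numeric(rec$delay_days),
                      matrix(p, nrow = 1), ss, err)[1]
}
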