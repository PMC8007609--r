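#' Cohort configuration for synthetic studies
#'
#' Defines the generative conditions of a simulated study: number of
#' subjects (3 sessions each, 96 trials per session from the mean-matched
#' trial sets), the generating model, group-level means, and the trait/state
#' decomposition of individual differences. Each subject's session-specific
#' parameter is trait + state: trait ~ N(0, trait_sd^2) drawn once per
#' subject, state ~ N(0, state_sd^2) drawn per session, both added to the
#' group mean on the estimation scale and clipped to the parameter's support
#' (clip events are counted). The implied test-retest reliability of a
#' parameter is rho = trait_sd^2 / (trait_sd^2 + state_sd^2).
#'
#' Defaults emulate the study scale (34 subjects) with group means close to
#' the lab-session softmax estimates (log_k about -4.1, beta about 0.42) and
#' trait/state SDs giving reliabilities near 0.9 for log_k and near 0.34 for
#' beta. DDM defaults put response times on the 1-3 s scale typical of the
#' task, with a larger non-decision time in the VR sessions
#' (`tau_session_offset`).
#'
#' @param n_subjects Number of subjects.
#' @param model Generating model.
#' @param group_means Named vector of group-level means (defaults per model).
#' @param trait_sd,state_sd Named vectors of between-subject and
#'   between-session SDs (defaults per model; 0 allowed).
#' @param tau_session_offset Added to tau in sessions 2 and 3 (VR motor
#'   overhead); DDM models only.
#' @param seed Integer seed.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_subjects = 34, model = c("softmax", "ddms", "ddml", "ddm0"),
                          group_means = NULL, trait_sd = NULL, state_sd = NULL,
                          tau_session_offset = 0.4, seed = 1L) {
  model <- match.arg(model)
  defaults <- switch(model,
    softmax = list(
      mean = c(log_k = -4.1, beta = 0.42),
      trait = c(log_k = 1.5, beta = 0.2),
      state = c(log_k = 0.5, beta = 0.28)),
    ddm0 = list(
      mean = c(v = 0.5, alpha = 2, tau = 0.8, z = 0.55),
      trait = c(v = 0.3, alpha = 0.3, tau = 0.15, z = 0.05),
      state = c(v = 0.1, alpha = 0.1, tau = 0.05, z = 0.02)),
    ddml = list(
      mean = c(log_k = -4.1, v_coeff = 0.25, alpha = 2, tau = 0.8, z = 0.55),
      trait = c(log_k = 1.5, v_coeff = 0.08, alpha = 0.3, tau = 0.15, z = 0.05),
      state = c(log_k = 0.5, v_coeff = 0.04, alpha = 0.1, tau = 0.05, z = 0.02)),
    ddms = list(
      mean = c(log_k = -4.1, v_coeff = 0.3, v_max = 2.5, alpha = 2,
               tau = 0.8, z = 0.55),
      trait = c(log_k = 1.5, v_coeff = 0.1, v_max = 0.5, alpha = 0.3,
                tau = 0.15, z = 0.05),
      state = c(log_k = 0.5, v_coeff = 0.05, v_max = 0.2, alpha = 0.1,
                tau = 0.05, z = 0.02)))
  pn <- model_params(model)
  gm <- defaults$mean; tr <- defaults$trait; st <- defaults$state
  if (!is.null(group_means)) gm[names(group_means)] <- group_means
  if (!is.null(trait_sd)) tr[names(trait_sd)] <- trait_sd
  if (!is.null(state_sd)) st[names(state_sd)] <- state_sd
  stopifnot(all(tr >= 0), all(st >= 0))
  structure(list(n_subjects = as.integer(n_subjects), sessions = 3L,
                 model = model, group_means = gm[pn], trait_sd = tr[pn],
                 state_sd = st[pn], tau_session_offset = tau_session_offset,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Implied theoretical reliability of each parameter
#'
#' rho = trait_sd^2 / (trait_sd^2 + state_sd^2); 1 when state_sd = 0.
#'
#' @param config A [cohort_config()].
#' @return Named vector of reliabilities in [0, 1].
#' @export
theoretical_reliability <- function(config) {
  v <- config$trait_sd^2
  w <- config$state_sd^2
  ifelse(v + w == 0, 1, v / (v + w))
}

# draw subject x session true parameter values (trait + state, clipped)
.draw_true_params <- function(config) {
  pn <- model_params(config$model)
  b <- param_bounds(config$model)
  n <- config$n_subjects
  clip_events <- 0L
  out <- vector("list", config$sessions)
  trait <- sapply(pn, function(p) stats::rnorm(n, 0, config$trait_sd[p]))
  for (s in seq_len(config$sessions)) {
    state <- sapply(pn, function(p) stats::rnorm(n, 0, config$state_sd[p]))
    th <- matrix(rep(config$group_means, each = n), n, length(pn),
                 dimnames = list(NULL, pn)) + trait + state
    if (config$model != "softmax" && s > 1)
      th[, "tau"] <- th[, "tau"] + config$tau_session_offset
    lo <- matrix(rep(b["lower", ] + 1e-3, each = n), n, length(pn))
    hi <- matrix(rep(b["upper", ] - 1e-3, each = n), n, length(pn))
    clip_events <- clip_events + sum(th < lo | th > hi)
    out[[s]] <- pmin(pmax(th, lo), hi)
  }
  list(params = out, n_clipped = clip_events)
}

#' Simulate choices from the hyperbolic/softmax model
#'
#' Each trial's choice is Bernoulli with the softmax LL probability at the
#' subject-session parameters; RTs are log-normal nuisance draws (softmax
#' fitting ignores them, but the files stay schema-complete).
#'
#' @param params Matrix subjects x (log_k, beta) of true values.
#' @param trials Data frame with `delay_days`, `ll_amount` (one session's
#'   96 trials, already ordered for presentation).
#' @param ss_amount Fixed smaller-sooner amount.
#' @return For each subject a data frame of `choice` (1 = LL) and `rt` (s).
#' @export
simulate_choices_softmax <- function(params, trials, ss_amount = 20) {
  lapply(seq_len(nrow(params)), function(i) {
    sv <- subjective_value(trials$ll_amount, trials$delay_days,
                           params[i, "log_k"])
    p <- softmax_p_ll(ss_amount, sv, params[i, "beta"])
    data.frame(choice = stats::rbinom(nrow(trials), 1, p),
               rt = stats::rlnorm(nrow(trials), log(1.2), 0.35))
  })
}

#' Simulate single diffusion trials by Euler-Maruyama
#'
#' Unit-diffusion random walk from z * alpha with time step `dt` until a
#' boundary is reached; the response time is the hitting time plus tau and
#' the sign of the returned rt encodes the boundary (positive = upper = LL).
#' Paths not absorbed within `tmax` are resampled and counted.
#'
#' @param v Drift rate(s), one per trial (scalar recycled).
#' @param n Number of trials (defaults to `length(v)`).
#' @param alpha,tau,z DDM parameters.
#' @param dt Euler step (s).
#' @param tmax Resampling horizon (s).
#' @param seed Integer seed for the simulator's own RNG stream.
#' @return List with signed `rt` vector and `n_resampled`.
#' @export
simulate_ddm_trial <- function(v, n = length(v), alpha, tau, z, dt = 1e-4,
                               tmax = 60, seed = 1) {
  stopifnot(alpha > 0, tau > 0, z > 0, z < 1, dt > 0)
  res <- sim_ddm_cpp(as.integer(n), as.numeric(v), alpha, tau, z, dt, tmax,
                     as.numeric(seed))
  if (res$n_resampled > 0.001 * n)
    warning(sprintf("%d of %d paths resampled (no boundary hit by %gs)",
                    res$n_resampled, n, tmax))
  res
}

#' Simulate a complete synthetic study
#'
#' Builds the three mean-matched trial sets, assigns them to sessions by a
#' Latin square, draws subject x session true parameters from the
#' trait/state model and generates behavior from the configured model
#' (softmax choices with nuisance RTs, or full diffusion trials). Returns
#' the trial-level table in the on-disk schema together with the exact
#' ground truth.
#'
#' @param config A [cohort_config()].
#' @return List with `choices` (data frame, one row per trial),
#'   `ground_truth` (list: per-session true parameter matrices, set
#'   assignment, clip count) and `trial_sets`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  sets <- build_trial_sets(seed = config$seed)
  assign <- shuffle_presentation(sets, config$n_subjects,
                                 seed = config$seed + 1L)
  truth <- .draw_true_params(config)
  pn <- model_params(config$model)
  sess_labels <- .SESSIONS

  rows <- vector("list", nrow(assign))
  for (r in seq_len(nrow(assign))) {
    i <- assign$subject[r]; s <- assign$session[r]
    tset <- sets[[assign$set_id[r] + 1L]]
    trials <- tset$trials[assign$order[[r]], , drop = FALSE]
    th <- truth$params[[s]][i, , drop = TRUE]
    if (config$model == "softmax") {
      beh <- simulate_choices_softmax(matrix(th, 1, length(pn),
                                             dimnames = list(NULL, pn)),
                                      trials)[[1]]
    } else {
      sv <- subjective_value(trials$ll_amount, trials$delay_days,
                             if ("log_k" %in% pn) th["log_k"] else 0)
      vt <- switch(config$model,
        ddm0 = rep(th["v"], nrow(trials)),
        ddml = drift_rate(20, sv, "linear", as.list(th)),
        ddms = drift_rate(20, sv, "sigmoid", as.list(th)))
      sim <- simulate_ddm_trial(vt, alpha = th[["alpha"]], tau = th[["tau"]],
                                z = th[["z"]],
                                seed = config$seed * 10000 + i * 100 + s)
      beh <- data.frame(choice = as.integer(sim$rt > 0), rt = abs(sim$rt))
    }
    rows[[r]] <- data.frame(
      subject_id = sprintf("S%02d", i), session = sess_labels[s],
      trial_index = seq_len(nrow(trials)) - 1L, set_id = tset$set_id,
      ss_amount = 20, ll_amount = trials$ll_amount,
      delay_days = trials$delay_days, choice = beh$choice,
      rt = round(beh$rt, 4))
  }
  choices <- do.call(rbind, rows)
  rownames(choices) <- NULL
  list(choices = validate_choice_records(choices),
       ground_truth = list(params = truth$params,
                           n_clipped = truth$n_clipped,
                           assignment = assign[, c("subject", "session", "set_id")],
                           model = config$model, config = config),
       trial_sets = sets)
}

#' Simulate electrodermal recordings with a known ground truth
#'
#' Tonic skin conductance level: baseline + a multiplicative step of size
#' `vr_step` at VR entry (start of phase F, persisting through S) + a slow
#' linear drift + Gaussian noise, sampled at 1 Hz over three 5-minute phases
#' (B, F, S). Spontaneous SCR events are Poisson per 1-s sample with a
#' per-minute rate that steps from `phasic_rate_base` to `phasic_rate_vr`
#' at VR entry.
#'
#' @param n_subjects Number of subjects.
#' @param baseline_level Tonic level during baseline (micro-Siemens).
#' @param vr_step Fractional SCL step at VR entry (0.3 = +30 percent).
#' @param phasic_rate_base,phasic_rate_vr Spontaneous SCR rates (events per
#'   minute) before/after VR entry.
#' @param drift_per_min Linear tonic drift (micro-Siemens per minute).
#' @param noise_sd SD of the additive Gaussian noise (micro-Siemens).
#' @param session Session label for the output table.
#' @param seed Integer seed.
#' @return Data frame in the EDA schema (`subject_id, session, time_s,
#'   scl_uS, scr_event, phase`) with attribute `ground_truth`.
#' @export
simulate_eda <- function(n_subjects = 26, baseline_level = 8, vr_step = 0.3,
                         phasic_rate_base = 4, phasic_rate_vr = 6,
                         drift_per_min = 0.02, noise_sd = 0.25,
                         session = "vr_neutral", seed = 1L) {
  set.seed(as.integer(seed))
  t <- 0:899                       # 1 Hz, three 5-min phases
  phase <- rep(c("B", "F", "S"), each = 300)
  vr <- t >= 300
  out <- lapply(seq_len(n_subjects), function(i) {
    lev <- baseline_level * stats::rlnorm(1, 0, 0.2)
    scl <- lev * (1 + vr_step * vr) + drift_per_min * t / 60 +
      stats::rnorm(length(t), 0, noise_sd)
    rate <- ifelse(vr, phasic_rate_vr, phasic_rate_base) / 60
    data.frame(subject_id = sprintf("S%02d", i), session = session,
               time_s = t, scl_uS = pmax(scl, 0.05),
               scr_event = stats::rpois(length(t), rate) > 0,
               phase = phase)
  })
  df <- do.call(rbind, out)
  df$scr_event <- as.integer(df$scr_event)
  attr(df, "ground_truth") <- list(vr_step = vr_step,
                                   phasic_rate_base = phasic_rate_base,
                                   phasic_rate_vr = phasic_rate_vr)
  df
}
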