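#' Prior specification for the hierarchical models
#'
#' Group-level means carry uniform priors over the numerically plausible
#' parameter ranges (the same ranges that truncate the subject-level
#' Gaussians); group-level precisions carry Gamma(0.001, 0.001) priors.
#'
#' @param model Model name; selects which parameters are included.
#' @return List with `bounds` (2 x P matrix, rows lower/upper),
#'   `gamma_shape`, `gamma_rate`.
#' @export
prior_spec <- function(model = c("softmax", "ddm0", "ddml", "ddms")) {
  model <- match.arg(model)
  list(bounds = param_bounds(model), gamma_shape = 0.001, gamma_rate = 0.001)
}

# Flatten a list of prepared sessions (or a signed-rt data frame) into the
# arrays the C++ likelihood consumes.
.assemble_fit_data <- function(prepared) {
  if (inherits(prepared, "prepared_session")) prepared <- list(prepared)
  if (is.data.frame(prepared)) {
    rec <- prepared
  } else {
    rec <- do.call(rbind, lapply(prepared, function(p) {
      if (inherits(p, "prepared_session")) p$records else p
    }))
  }
  subj_ids <- unique(rec$subject_id)
  list(
    subj = match(rec$subject_id, subj_ids) - 1L,
    rt = as.numeric(rec$rt),
    amount = as.numeric(rec$ll_amount),
    delay = as.numeric(rec$delay_days),
    ss = if ("ss_amount" %in% names(rec)) rec$ss_amount[1] else 20,
    subject_ids = subj_ids,
    session = if ("session" %in% names(rec)) unique(as.character(rec$session)) else NA_character_,
    n_subjects = length(subj_ids)
  )
}

# Choice-informed starting value for log_k: the log discount rate at which
# the predicted larger-later choice fraction (softmax with a moderate
# inverse temperature) matches the observed fraction. Monotone in log_k, so
# bisection; keeps chains off the flat likelihood ridge where exp(log_k) is
# negligible and the drift mapping alone must explain the choices.
.init_log_k <- function(rt, amount, delay, ss) {
  p_obs <- mean(rt > 0)
  pred <- function(lk)
    mean(stats::plogis(0.5 * (amount / (1 + exp(lk) * delay) - ss)))
  if (p_obs >= pred(-12)) return(-8)
  if (p_obs <= pred(1)) return(0.5)
  stats::uniroot(function(lk) pred(lk) - p_obs, c(-12, 1))$root
}

# log normalizing constant of a normal truncated to [lb, ub]
.log_trunc_z <- function(mu, sd, lb, ub) {
  z <- stats::pnorm(ub, mu, sd) - stats::pnorm(lb, mu, sd)
  ifelse(z > 0, log(z), -Inf)
}

#' Fit a hierarchical Bayesian model to all subjects of one session
#'
#' Subject-level parameters are drawn from group-level Gaussians (mean and
#' precision estimated from the data) truncated to each parameter's support;
#' group means carry uniform priors over those supports and group precisions
#' Gamma(0.001, 0.001) priors. The posterior is sampled by adaptive
#' Metropolis-within-Gibbs: random-walk updates for every subject-level
#' parameter (vectorized across subjects), the group means and the group
#' log-precisions, with per-quantity proposal scales tuned toward a 0.44
#' acceptance rate during warmup and frozen afterwards. Convergence is
#' summarized by rank-normalized split-chain R-hat for every sampled
#' quantity; any R-hat above 1.01 flags the fit as non-converged (returned
#' with a warning, not an error).
#'
#' @param model `"softmax"`, `"ddm0"`, `"ddml"` or `"ddms"`.
#' @param prepared List of `prepared_session` objects (one per subject, same
#'   session) or one data frame of signed-rt records for all subjects.
#' @param priors A [prior_spec()].
#' @param mcmc List with `chains` (>= 2), `warmup`, `draws` (post-warmup
#'   iterations per chain), `seed`, and optionally `err` (wfpt tolerance).
#' @return A `hier_fit` object: posterior draws for group means, group SDs
#'   and subject-level parameters (per chain), deviance draws, R-hat per
#'   quantity, convergence status, settings and data.
#' @export
fit_hierarchical <- function(model, prepared, priors = prior_spec(model),
                             mcmc = list()) {
  model <- match.arg(model, c("softmax", "ddm0", "ddml", "ddms"))
  cfg <- utils::modifyList(
    list(chains = 4L, warmup = 1000L, draws = 4000L, seed = 1L, err = 1e-9),
    mcmc)
  if (cfg$chains < 2) stop("at least 2 chains are required")
  dat <- .assemble_fit_data(prepared)
  if (dat$n_subjects < 2) stop("at least 2 subjects are required")

  pn <- model_params(model)
  P <- length(pn)
  n <- dat$n_subjects
  lb <- priors$bounds["lower", ]
  ub <- priors$bounds["upper", ]
  code <- .MODEL_CODE[[model]]
  is_ddm <- model != "softmax"
  # per-subject smallest absolute RT bounds tau from above
  min_rt <- tapply(abs(dat$rt), dat$subj, min)

  loglik <- function(theta)
    loglik_subjects_cpp(code, dat$subj, dat$rt, dat$amount, dat$delay,
                        theta, dat$ss, cfg$err)

  set.seed(as.integer(cfg$seed) %% .Machine$integer.max)
  chain_seeds <- sample.int(2^30, cfg$chains)
  iters <- cfg$warmup + cfg$draws

  mu_draws <- array(NA_real_, c(cfg$draws, P, cfg$chains),
                    dimnames = list(NULL, pn, NULL))
  sd_draws <- mu_draws
  th_draws <- array(NA_real_, c(cfg$draws, n, P, cfg$chains),
                    dimnames = list(NULL, dat$subject_ids, pn, NULL))
  dev_draws <- matrix(NA_real_, cfg$draws, cfg$chains)

  for (ch in seq_len(cfg$chains)) {
    set.seed(chain_seeds[ch])
    # dispersed initials: chain-specific quantile of each support
    frac <- 0.35 + 0.3 * (ch - 1) / max(1, cfg$chains - 1)
    mu <- lb + frac * (ub - lb)
    names(mu) <- pn
    if (is_ddm) {
      # start non-decision time safely below every subject's fastest trial
      mu["tau"] <- max(lb["tau"] + 0.01, min(0.6 * min(min_rt), 1))
      if ("alpha" %in% pn) mu["alpha"] <- 1.5
      if ("v_coeff" %in% pn) mu["v_coeff"] <- 0.2 + 0.1 * frac
      if ("v" %in% pn) mu["v"] <- 0.5
      if ("v_max" %in% pn) mu["v_max"] <- 2 + frac
      mu["z"] <- 0.5
    }
    lk0 <- NULL
    if ("log_k" %in% pn) {
      lk0 <- vapply(seq_len(n) - 1L, function(i) {
        sel <- dat$subj == i
        .init_log_k(dat$rt[sel], dat$amount[sel], dat$delay[sel], dat$ss)
      }, 0)
      mu["log_k"] <- mean(lk0) + 0.3 * (frac - 0.5)
    }
    sdv <- 0.05 * (ub - lb)
    sdv[pn == "z"] <- 0.05
    if ("log_k" %in% pn) sdv[pn == "log_k"] <- max(stats::sd(lk0), 0.5)
    lam <- 1 / sdv^2

    theta <- matrix(rep(mu, each = n), n, P, dimnames = list(NULL, pn))
    if (!is.null(lk0)) theta[, "log_k"] <- lk0
    theta <- theta + matrix(stats::rnorm(n * P), n, P) * 0.2 *
      matrix(rep(sdv, each = n), n, P)
    theta <- pmin(pmax(theta, matrix(rep(lb + 1e-4 * (ub - lb), each = n), n, P)),
                  matrix(rep(ub - 1e-4 * (ub - lb), each = n), n, P))
    if (is_ddm)
      theta[, "tau"] <- pmin(theta[, "tau"], 0.8 * min_rt)

    ll <- loglik(theta)
    if (any(!is.finite(ll)))
      stop("non-finite likelihood at initial values; check the data")

    ls_th <- matrix(log(0.1 * (ub - lb)), n, P, byrow = TRUE)
    ls_mu <- log(0.05 * (ub - lb))
    ls_lam <- rep(log(0.5), P)

    for (it in seq_len(iters)) {
      adapt <- it <= cfg$warmup
      eta <- if (adapt) min(0.25, 2 / sqrt(it)) else 0
      sig <- 1 / sqrt(lam)

      for (p in seq_len(P)) {
        # --- subject-level update, vectorized across subjects ---
        prop <- theta
        prop[, p] <- theta[, p] + stats::rnorm(n) * exp(ls_th[, p])
        inside <- prop[, p] > lb[p] & prop[, p] < ub[p]
        ll_new <- rep(-Inf, n)
        if (any(inside)) {
          prop[!inside, p] <- theta[!inside, p]
          ll_all <- loglik(prop)
          ll_new[inside] <- ll_all[inside]
        }
        ratio <- ll_new - ll +
          stats::dnorm(prop[, p], mu[p], sig[p], log = TRUE) -
          stats::dnorm(theta[, p], mu[p], sig[p], log = TRUE)
        ratio[!inside] <- -Inf
        acc <- log(stats::runif(n)) < ratio
        theta[acc, p] <- prop[acc, p]
        ll[acc] <- ll_new[acc]
        if (adapt)
          ls_th[, p] <- ls_th[, p] + eta * ((acc * 1) - 0.44)

        # independence refresh from the truncated group prior: lets weakly
        # identified subjects (flat likelihood ridges, e.g. all-SS
        # responders) jump between modes the random walk cannot cross.
        # Proposal density equals the prior, so the MH ratio is the
        # likelihood ratio alone.
        if (it %% 5 == 0) {
          pa <- stats::pnorm(lb[p], mu[p], sig[p])
          pb <- stats::pnorm(ub[p], mu[p], sig[p])
          prop <- theta
          prop[, p] <- stats::qnorm(pa + stats::runif(n) * (pb - pa),
                                    mu[p], sig[p])
          okp <- is.finite(prop[, p]) & prop[, p] > lb[p] & prop[, p] < ub[p]
          prop[!okp, p] <- theta[!okp, p]
          ll_new <- loglik(prop)
          acc <- okp & (log(stats::runif(n)) < ll_new - ll)
          theta[acc, p] <- prop[acc, p]
          ll[acc] <- ll_new[acc]
        }

        # --- group mean ---
        mp <- mu[p] + stats::rnorm(1) * exp(ls_mu[p])
        if (mp > lb[p] && mp < ub[p]) {
          lr <- sum(stats::dnorm(theta[, p], mp, sig[p], log = TRUE)) -
            sum(stats::dnorm(theta[, p], mu[p], sig[p], log = TRUE)) -
            n * (.log_trunc_z(mp, sig[p], lb[p], ub[p]) -
                   .log_trunc_z(mu[p], sig[p], lb[p], ub[p]))
          a <- is.finite(lr) && log(stats::runif(1)) < lr
          if (a) mu[p] <- mp
        } else a <- FALSE
        if (adapt) ls_mu[p] <- ls_mu[p] + eta * (a - 0.44)

        # --- group precision (random walk on log scale) ---
        llam <- log(lam[p]) + stats::rnorm(1) * exp(ls_lam[p])
        lam_p <- exp(llam)
        sig_p <- 1 / sqrt(lam_p)
        lr <- sum(stats::dnorm(theta[, p], mu[p], sig_p, log = TRUE)) -
          sum(stats::dnorm(theta[, p], mu[p], sig[p], log = TRUE)) -
          n * (.log_trunc_z(mu[p], sig_p, lb[p], ub[p]) -
                 .log_trunc_z(mu[p], sig[p], lb[p], ub[p])) +
          stats::dgamma(lam_p, priors$gamma_shape, priors$gamma_rate,
                        log = TRUE) -
          stats::dgamma(lam[p], priors$gamma_shape, priors$gamma_rate,
                        log = TRUE) +
          llam - log(lam[p])      # Jacobian of the log transform
        a <- is.finite(lr) && log(stats::runif(1)) < lr
        if (a) { lam[p] <- lam_p; sig[p] <- sig_p }
        if (adapt) ls_lam[p] <- ls_lam[p] + eta * (a - 0.44)
      }

      # joint refresh of (log_k, v_coeff): the two parameters trade off
      # (a sign flip in v_coeff mirrors the value-difference mapping that a
      # shifted log_k produces for near-deterministic responders), so modes
      # are crossed only by moving both at once. Independence proposal from
      # the truncated group priors; MH ratio = likelihood ratio.
      if (it %% 5 == 2 && all(c("log_k", "v_coeff") %in% pn)) {
        pair <- match(c("log_k", "v_coeff"), pn)
        prop <- theta
        for (p in pair) {
          pa <- stats::pnorm(lb[p], mu[p], 1 / sqrt(lam[p]))
          pb <- stats::pnorm(ub[p], mu[p], 1 / sqrt(lam[p]))
          prop[, p] <- stats::qnorm(pa + stats::runif(n) * (pb - pa),
                                    mu[p], 1 / sqrt(lam[p]))
        }
        okp <- rowSums(is.finite(prop[, pair, drop = FALSE])) == 2
        for (p in pair) prop[!okp, p] <- theta[!okp, p]
        ll_new <- loglik(prop)
        acc <- okp & (log(stats::runif(n)) < ll_new - ll)
        for (p in pair) theta[acc, p] <- prop[acc, p]
        ll[acc] <- ll_new[acc]
      }

      if (it > cfg$warmup) {
        k <- it - cfg$warmup
        mu_draws[k, , ch] <- mu
        sd_draws[k, , ch] <- 1 / sqrt(lam)
        th_draws[k, , , ch] <- theta
        dev_draws[k, ch] <- -2 * sum(ll)
      }
    }
  }

  rh <- c(
    stats::setNames(vapply(seq_len(P), function(p)
      rhat(mu_draws[, p, ]), 0), paste0("mu_", pn)),
    stats::setNames(vapply(seq_len(P), function(p)
      rhat(sd_draws[, p, ]), 0), paste0("sd_", pn)),
    stats::setNames(
      as.vector(vapply(seq_len(P), function(p)
        vapply(seq_len(n), function(i) rhat(th_draws[, i, p, ]), 0),
        numeric(n))),
      as.vector(outer(dat$subject_ids, pn,
                      function(s, q) paste0("theta_", q, "[", s, "]"))))
  )
  converged <- all(is.na(rh) | rh <= 1.01)
  if (!converged)
    warning("R-hat > 1.01 for ",
            sum(rh > 1.01, na.rm = TRUE),
            " quantities; fit flagged as non-converged")

  structure(list(
    model = model, session = dat$session, subject_ids = dat$subject_ids,
    draws = list(mu = mu_draws, sd = sd_draws, theta = th_draws),
    deviance = dev_draws, rhat = rh, converged = converged,
    settings = cfg, seed = cfg$seed, data = dat, priors = priors
  ), class = "hier_fit")
}

#' @export
print.hier_fit <- function(x, ...) {
  cat(sprintf("Hierarchical %s fit: %d subjects, session %s\n", x$model,
              length(x$subject_ids), paste(x$session, collapse = "/")))
  cat(sprintf("  chains=%d warmup=%d draws=%d seed=%s | max R-hat %.4f (%s)\n",
              x$settings$chains, x$settings$warmup, x$settings$draws,
              x$settings$seed, max(x$rhat, na.rm = TRUE),
              if (x$converged) "converged" else "NOT converged"))
  s <- group_posterior_summary(x)
  print(s, digits = 3)
  invisible(x)
}

#' Pooled group-mean posterior draws for one parameter
#'
#' @param fit A `hier_fit`.
#' @param param Parameter name.
#' @return Numeric vector of pooled (all chains) posterior draws.
#' @export
group_mean_draws <- function(fit, param) {
  stopifnot(inherits(fit, "hier_fit"), param %in% model_params(fit$model))
  as.vector(fit$draws$mu[, param, ])
}

#' Posterior means of subject-level parameters
#'
#' @param fit A `hier_fit`.
#' @return Matrix subjects x parameters of posterior means.
#' @export
subject_posterior_means <- function(fit) {
  stopifnot(inherits(fit, "hier_fit"))
  apply(fit$draws$theta, c(2, 3), mean)
}

#' Posterior summary of the group-level means
#'
#' @param fit A `hier_fit`.
#' @param prob Central interval mass.
#' @return Data frame with mean and central interval per parameter.
#' @export
group_posterior_summary <- function(fit, prob = 0.95) {
  pn <- model_params(fit$model)
  a <- (1 - prob) / 2
  do.call(rbind, lapply(pn, function(p) {
    d <- group_mean_draws(fit, p)
    data.frame(parameter = p, mean = mean(d),
               lower = unname(stats::quantile(d, a)),
               upper = unname(stats::quantile(d, 1 - a)),
               rhat = unname(fit$rhat[paste0("mu_", p)]))
  }))
}

#' Rank-normalized split-chain potential scale reduction factor
#'
#' Gelman-Rubin R-hat in the rank-normalized split-chain variant: each chain
#' is split in half, pooled draws are replaced by normal scores of their
#' ranks, and the classic between/within variance ratio is computed on the
#' result. Values between 1 and 1.01 are treated as acceptable elsewhere in
#' the package. If every chain has zero internal variance the statistic is
#' undefined and `NA` is returned.
#'
#' @param draws Matrix of posterior draws, iterations x chains (>= 2 chains,
#'   >= 4 draws each).
#' @return Scalar R-hat (or `NA` if undefined).
#' @export
rhat <- function(draws) {
  draws <- as.matrix(draws)
  if (ncol(draws) < 2) stop("at least 2 chains are required")
  if (nrow(draws) < 4) stop("at least 4 draws per chain are required")
  half <- floor(nrow(draws) / 2)
  split_chains <- cbind(draws[seq_len(half), , drop = FALSE],
                        draws[half + seq_len(half), , drop = FALSE])
  if (all(apply(split_chains, 2, stats::var) == 0)) return(NA_real_)
  r <- matrix(rank(split_chains, ties.method = "average"),
              nrow(split_chains), ncol(split_chains))
  zs <- stats::qnorm((r - 3 / 8) / (length(r) + 1 / 4))
  m <- ncol(zs); ndraw <- nrow(zs)
  W <- mean(apply(zs, 2, stats::var))
  B <- ndraw * stats::var(colMeans(zs))
  if (W == 0) return(NA_real_)
  sqrt(((ndraw - 1) / ndraw * W + B / ndraw) / W)
}

#' Deviance information criterion of a hierarchical fit
#'
#' Dbar is the posterior mean of -2 x (sum of subject-level data
#' log-likelihoods); the plug-in deviance D-hat evaluates the likelihood at
#' the posterior means of the subject-level parameters; pD = Dbar - D-hat
#' and DIC = Dbar + pD.
#'
#' @param fit A `hier_fit`.
#' @param data Optional replacement data (defaults to the data the fit was
#'   run on).
#' @return List with `dic`, `pd`, `dbar`.
#' @export
dic <- function(fit, data = NULL) {
  stopifnot(inherits(fit, "hier_fit"))
  dat <- if (is.null(data)) fit$data else .assemble_fit_data(data)
  dbar <- mean(fit$deviance)
  thbar <- subject_posterior_means(fit)
  ll_hat <- loglik_subjects_cpp(.MODEL_CODE[[fit$model]], dat$subj, dat$rt,
                                dat$amount, dat$delay, thbar, dat$ss,
                                fit$settings$err)
  dhat <- -2 * sum(ll_hat)
  if (!is.finite(dhat)) stop("non-finite deviance at the posterior mean")
  pd <- dbar - dhat
  list(dic = dbar + pd, pd = pd, dbar = dbar)
}

#' Serialize a fit: tidy group-level draws plus a JSON summary
#'
#' Writes `<prefix>_draws.csv` with columns chain, draw, parameter, value
#' (group-level means and SDs) and `<prefix>_summary.json` with model,
#' session, DIC, pD, R-hat per quantity, seed and sampler settings.
#'
#' @param fit A `hier_fit`.
#' @param prefix Output path prefix.
#' @return Invisibly, the two paths.
#' @export
write_fit_draws <- function(fit, prefix) {
  stopifnot(inherits(fit, "hier_fit"))
  pn <- model_params(fit$model)
  nd <- dim(fit$draws$mu)[1]
  nc <- dim(fit$draws$mu)[3]
  tidy <- do.call(rbind, lapply(seq_len(nc), function(ch)
    do.call(rbind, lapply(pn, function(p)
      data.frame(chain = ch, draw = seq_len(nd),
                 parameter = c(rep(paste0("mu_", p), nd),
                               rep(paste0("sd_", p), nd)),
                 value = c(fit$draws$mu[, p, ch],
                           fit$draws$sd[, p, ch]))))))
  p_csv <- paste0(prefix, "_draws.csv")
  utils::write.csv(tidy, p_csv, row.names = FALSE)
  d <- dic(fit)
  p_json <- paste0(prefix, "_summary.json")
  jsonlite::write_json(
    list(model = fit$model, session = fit$session, dic = d$dic, pd = d$pd,
         rhat = as.list(fit$rhat), converged = fit$converged,
         seed = fit$seed,
         settings = fit$settings[c("chains", "warmup", "draws")]),
    p_json, auto_unbox = TRUE, digits = NA)
  invisible(c(p_csv, p_json))
}

#' Rank candidate models of one session by DIC
#'
#' @param fits List of `hier_fit` objects sharing data and session.
#' @return Data frame with model, dic, pd and rank (1 = lowest DIC; ties
#'   share the minimum rank).
#' @export
compare_models <- function(fits) {
  stopifnot(length(fits) >= 1, all(vapply(fits, inherits, TRUE, "hier_fit")))
  sess <- unique(vapply(fits, function(f) paste(f$session, collapse = "/"), ""))
  if (length(sess) > 1) stop("fits come from different sessions: ",
                             paste(sess, collapse = " vs "))
  tab <- do.call(rbind, lapply(fits, function(f) {
    d <- dic(f)
    data.frame(model = f$model, dic = d$dic, pd = d$pd, dbar = d$dbar)
  }))
  tab$rank <- rank(tab$dic, ties.method = "min")
  tab[order(tab$dic), ]
}
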