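test_that("hyperbolic subjective value matches direct evaluation", {
  expect_equal(subjective_value(20, 0, -3), 20)      # delay-0 identity
  expect_equal(subjective_value(40, 1, 0), 20)       # k=1 halves at 1 day
  # group-mean-scale example: direct arithmetic oracle
  expect_equal(subjective_value(40, 30, -4.083),
               40 / (1 + exp(-4.083) * 30))
  expect_equal(round(subjective_value(40, 30, -4.083), 1), 26.6)
  # strictly decreasing in delay
  d <- subjective_value(40, 0:122, -2)
  expect_true(all(diff(d) < 0))
})

test_that("softmax choice probability is symmetric, bounded and monotone", {
  expect_equal(softmax_p_ll(13, 57, 0), 0.5)         # beta 0 -> random
  expect_equal(softmax_p_ll(25, 25, 3), 0.5)         # equal values
  expect_equal(round(softmax_p_ll(20, 25, 0.417), 3), 0.889)
  # overflow safety and monotonicity in the value difference
  p <- softmax_p_ll(20, seq(-500, 500, by = 50), 5)
  expect_true(all(p >= 0 & p <= 1))
  expect_true(all(diff(p) >= 0))
})

test_that("drift mappings: constant, linear, sigmoid with asymptote", {
  expect_equal(drift_rate(10, 10, "sigmoid",
                          list(v_coeff = 2, v_max = 3)), 0)
  expect_equal(drift_rate(0, 4, "linear", list(v_coeff = 0.5)), 2)
  expect_equal(drift_rate(5, 5, "constant", list(v = 1.3)), 1.3)
  # sigmoid saturates at +/- v_max
  expect_equal(drift_rate(0, 1e6, "sigmoid",
                          list(v_coeff = 1, v_max = 2.5)), 2.5)
  expect_equal(drift_rate(1e6, 0, "sigmoid",
                          list(v_coeff = 1, v_max = 2.5)), -2.5)
  expect_error(drift_rate(0, 1, "sigmoid", list(v_coeff = 1)), "v_max")
})

test_that("sigmoid mapping reduces to a linear mapping for small inputs", {
  # S(m) = v_max * tanh(m / 2), so far from saturation the sigmoid model
  # behaves as a linear mapping with effective coefficient
  # v_coeff * v_max / 2
  dv <- seq(-1e-4, 1e-4, length.out = 11)
  m <- drift_rate(0, dv, "linear", list(v_coeff = 2))
  sig <- drift_rate(0, dv, "sigmoid", list(v_coeff = 2, v_max = 1e6))
  expect_equal(sig, 1e6 * tanh(m / 2), tolerance = 1e-9)
  expect_equal(sig, m * 1e6 / 2, tolerance = 1e-6)
})

test_that("wfpt density is a proper density with the reflection symmetry", {
  f <- function(t, v, a, tau, z) exp(wfpt_logdensity(t, v, a, tau, z))
  for (par in list(c(1, 2, 0.3, 0.5), c(-0.8, 1.2, 0.4, 0.35),
                   c(0, 1.5, 0.2, 0.6))) {
    up <- stats::integrate(function(t) f(t, par[1], par[2], par[3], par[4]),
                           par[3], par[3] + 60, rel.tol = 1e-9)$value
    lo <- stats::integrate(function(t) f(-t, par[1], par[2], par[3], par[4]),
                           par[3], par[3] + 60, rel.tol = 1e-9)$value
    expect_gte(up + lo, 0.999)
    expect_lte(up + lo, 1.0001)
  }
  # v = 0, z = 0.5: both boundaries equally likely
  up <- stats::integrate(function(t) f(t, 0, 2, 0.3, 0.5), 0.3, 60)$value
  expect_equal(up, 0.5, tolerance = 1e-6)
  # exact reflection identity wfpt(+t | v, z) = wfpt(-t | -v, 1-z)
  ts <- c(0.5, 0.9, 1.7, 3.1)
  expect_equal(wfpt_logdensity(ts, 0.7, 1.5, 0.3, 0.35),
               wfpt_logdensity(-ts, -0.7, 1.5, 0.3, 0.65))
})

test_that("wfpt returns -Inf at or before the non-decision time", {
  expect_identical(wfpt_logdensity(c(0.3, 0.29, -0.1), 1, 2, 0.3, 0.5),
                   rep(-Inf, 3))
  expect_error(wfpt_logdensity(1, NaN, 2, 0.3, 0.5), "non-finite")
})

test_that("session log-likelihood composes per model and nests correctly", {
  rec <- make_records(50, seed = 9)
  prep <- preprocess_rts(rec, trim_fraction = 0)
  # softmax with beta 0: every trial contributes log(0.5)
  expect_equal(session_loglik("softmax", c(log_k = -4, beta = 0), prep),
               50 * log(0.5))
  # ddms with v_coeff = 0 equals ddm0 with v = 0
  lls <- session_loglik("ddms", c(log_k = -4, v_coeff = 0, v_max = 2,
                                  alpha = 2, tau = 0.2, z = 0.5), prep)
  ll0 <- session_loglik("ddm0", c(v = 0, alpha = 2, tau = 0.2, z = 0.5),
                        prep)
  expect_equal(lls, ll0)
  # a trial at or below tau drives the DDM likelihood to -Inf
  expect_identical(session_loglik("ddm0", c(v = 0, alpha = 2, tau = 5,
                                            z = 0.5), prep), -Inf)
})

test_that("likelihood prefers generating parameters over perturbed ones", {
  # cohort-level consistency: the average per-trial log-likelihood under
  # the generating parameters beats a global log_k shift of +/- 3 (for a
  # single near-deterministic responder the likelihood can be flat in
  # log_k, so the property is about the cohort, not every subject)
  cfg <- cohort_config(n_subjects = 6, model = "ddms", seed = 31)
  sim <- simulate_cohort(cfg)
  truth <- sim$ground_truth$params
  sess <- c("lab", "vr_neutral", "vr_gambling")
  total <- function(shift) {
    ll <- 0
    for (i in 1:6) for (s in 1:3) {
      d <- sim$choices[sim$choices$subject_id == sprintf("S%02d", i) &
                         sim$choices$session == sess[s], ]
      prep <- preprocess_rts(d, trim_fraction = 0)
      th <- truth[[s]][i, ]
      th["log_k"] <- th["log_k"] + shift
      ll <- ll + session_loglik("ddms", th, prep)
    }
    ll
  }
  ll_true <- total(0)
  expect_gt(ll_true, total(3))
  expect_gt(ll_true, total(-3))
})

test_that("simulated diffusion trials match the wfpt density", {
  s <- simulate_ddm_trial(v = 1, n = 2e4, alpha = 2, tau = 0.3, z = 0.5,
                          seed = 77)
  expect_equal(s$n_resampled, 0)
  # choice split matches the analytic upper-boundary probability
  # P(upper) = (1 - exp(-2 v a z)) / (1 - exp(-2 v a))
  p_up <- (1 - exp(-2 * 1 * 2 * 0.5)) / (1 - exp(-2 * 1 * 2))
  expect_lt(abs(mean(s$rt > 0) - p_up), 0.01)
  # density agreement at the histogram mode (upper boundary)
  x <- s$rt[s$rt > 0]
  h <- hist(x, breaks = seq(0.3, max(x) + 0.05, by = 0.05), plot = FALSE)
  i <- which.max(h$density)
  emp <- h$density[i] * length(x) / length(s$rt)
  thr <- mean(exp(wfpt_logdensity(
    seq(h$breaks[i], h$breaks[i + 1], length.out = 9), 1, 2, 0.3, 0.5)))
  expect_lt(abs(emp - thr) / thr, 0.05)
  # extreme drift: immediate upper-boundary absorption
  s2 <- simulate_ddm_trial(v = 50, n = 500, alpha = 1, tau = 0.3, z = 0.5,
                           seed = 78)
  expect_true(all(s2$rt > 0))
  expect_lt(mean(s2$rt), 0.35)
  # symmetry at v = 0
  s3 <- simulate_ddm_trial(v = 0, n = 1e4, alpha = 1.5, tau = 0.3, z = 0.5,
                           seed = 79)
  expect_lt(abs(mean(s3$rt > 0) - 0.5), 3 * 0.005)
})
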