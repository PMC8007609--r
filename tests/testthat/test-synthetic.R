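test_that("the default cohort has the study's dimensions", {
  cfg <- cohort_config(seed = 2)
  sim <- simulate_cohort(cfg)
  expect_equal(nrow(sim$choices), 34 * 3 * 96)
  expect_equal(length(unique(sim$choices$subject_id)), 34)
  expect_setequal(unique(sim$choices$session),
                  c("lab", "vr_neutral", "vr_gambling"))
  tab <- table(sim$choices$subject_id, sim$choices$session)
  expect_true(all(tab == 96))
})

test_that("cohort generation is deterministic and respects state_sd = 0", {
  cfg <- cohort_config(n_subjects = 5, model = "softmax", seed = 9,
                       state_sd = c(log_k = 0, beta = 0))
  s1 <- simulate_cohort(cfg)
  s2 <- simulate_cohort(cfg)
  expect_identical(s1$choices, s2$choices)
  gt <- s1$ground_truth$params
  expect_equal(gt[[1]], gt[[2]])      # identical across sessions
  expect_equal(gt[[1]], gt[[3]])
})

test_that("softmax choices track their analytic probabilities", {
  set.seed(10)
  trials <- build_trial_sets(seed = 1)[[1]]$trials
  # beta = 0: random choice
  p0 <- matrix(c(-4, 0), 1, 2, dimnames = list(NULL, c("log_k", "beta")))
  beh <- do.call(rbind, simulate_choices_softmax(
    p0[rep(1, 34), , drop = FALSE], trials))
  expect_equal(mean(beh$choice), 0.5, tolerance = 3 * 0.5 / sqrt(nrow(beh)))
  # negligible discounting with high consistency: LL on nearly every trial
  p1 <- matrix(c(-20, 10), 1, 2, dimnames = list(NULL, c("log_k", "beta")))
  beh1 <- simulate_choices_softmax(p1, trials)[[1]]
  expect_gte(mean(beh1$choice), 0.99)
  # per-cell choice frequencies within 3 binomial SEs of the softmax curve
  pm <- matrix(c(-4.1, 0.8), 1, 2, dimnames = list(NULL, c("log_k", "beta")))
  reps <- do.call(cbind, lapply(simulate_choices_softmax(
    pm[rep(1, 300), , drop = FALSE], trials), `[[`, "choice"))
  p_hat <- rowMeans(reps)
  p_true <- softmax_p_ll(20, subjective_value(trials$ll_amount,
                                              trials$delay_days, -4.1), 0.8)
  se <- sqrt(p_true * (1 - p_true) / 300)
  expect_true(all(abs(p_hat - p_true) <= pmax(3 * se, 0.005)))
})

test_that("trait/state structure yields the intended reliability of truths", {
  cfg9 <- cohort_config(n_subjects = 34, model = "softmax", seed = 12,
                        trait_sd = c(log_k = 1.5), state_sd = c(log_k = 0.5))
  expect_equal(unname(theoretical_reliability(cfg9)["log_k"]), 0.9)
  gt <- simulate_cohort(cfg9)$ground_truth$params
  m <- sapply(gt, function(g) g[, "log_k"])
  expect_gt(icc_agreement(m)$icc, 0.75)
  cfg2 <- cohort_config(n_subjects = 34, model = "softmax", seed = 12,
                        trait_sd = c(log_k = 0.5), state_sd = c(log_k = 1.0))
  expect_equal(unname(theoretical_reliability(cfg2)["log_k"]), 0.2)
  m2 <- sapply(simulate_cohort(cfg2)$ground_truth$params,
               function(g) g[, "log_k"])
  expect_lt(icc_agreement(m2)$icc, 0.55)
})

test_that("EDA generator honors its ground-truth step and rates", {
  eda <- simulate_eda(n_subjects = 8, vr_step = 0, drift_per_min = 0,
                      seed = 13)
  bins <- lapply(split(eda, eda$subject_id), bin_and_normalize)
  vr_means <- sapply(bins, function(b) mean(b$scl_pct[6:15]))
  expect_lt(abs(mean(vr_means)), 3)          # no step -> ~0% change
  eda30 <- simulate_eda(n_subjects = 8, vr_step = 0.3, drift_per_min = 0,
                        seed = 13)
  bins30 <- lapply(split(eda30, eda30$subject_id), bin_and_normalize)
  vr30 <- sapply(bins30, function(b) mean(b$scl_pct[6:15]))
  expect_equal(mean(vr30), 30, tolerance = 0.15 * 30)
  # constant phasic rate -> nSCR percent change about 0 across phases
  edap <- simulate_eda(n_subjects = 12, phasic_rate_base = 5,
                       phasic_rate_vr = 5, seed = 14)
  binsp <- lapply(split(edap, edap$subject_id), bin_and_normalize)
  nscr <- sapply(binsp, function(b) mean(b$nscr_pct[6:15]))
  expect_lt(abs(mean(nscr)), 15)
})
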