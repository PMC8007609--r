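test_that("indifference points recover a deterministic hyperbolic agent", {
  # agent with k = 0.01 (log_k = log(0.01)): at delay D the indifference
  # LL amount is exactly 20 * (1 + 0.01 * D)
  rec <- hyperbolic_agent_records(log(0.01), n_rep = 2, seed = 21)
  prof <- indifference_points(rec)
  grid_step <- diff(20 * seq(1.025, 3.85, length.out = 16))[1]  # 3.77 EUR
  for (i in seq_len(nrow(prof))) {
    a_true <- 20 * (1 + 0.01 * prof$delay_days[i])
    expect_lte(abs(prof$a_star[i] - a_true), grid_step)
  }
})

test_that("all-LL and all-SS responders clamp to the offer range", {
  rec <- make_records(96, choice = 1, seed = 22)
  prof <- indifference_points(rec)
  expect_true(all(prof$a_star == 20))
  expect_true(all(prof$status == "separated"))
  rec0 <- make_records(96, choice = 0, seed = 22)
  prof0 <- indifference_points(rec0)
  expect_true(all(prof0$a_star == 77))
})

test_that("a delay with a single distinct amount is marked unusable", {
  rec <- make_records(96, seed = 23)
  rec$ll_amount[rec$delay_days == 1] <- 40
  prof <- indifference_points(rec)
  expect_equal(prof$status[prof$delay_days == 1], "unusable")
  expect_true(is.na(prof$a_star[prof$delay_days == 1]))
})

test_that("AUC hits its closed-form anchors", {
  mk_prof <- function(a_star) {
    p <- data.frame(delay_days = c(1, 15, 29, 94, 108, 122),
                    a_star = a_star, status = "ok")
    attr(p, "ss_amount") <- 20
    class(p) <- c("indifference_profile", class(p))
    p
  }
  expect_equal(auc(mk_prof(rep(20, 6))), 1)      # no discounting
  # flat maximal discounting: trapezoid in closed form
  x <- c(0, c(1, 15, 29, 94, 108, 122) / 122)
  y <- c(1, rep(20 / 77, 6))
  a_exp <- sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2) / max(x)
  expect_equal(auc(mk_prof(rep(77, 6))), a_exp)
  # monotonicity: uniformly larger A* never increases AUC
  expect_lt(auc(mk_prof(rep(50, 6))), auc(mk_prof(rep(30, 6))))
})

test_that("hyperbolic-agent AUC matches the analytic integral within 2%", {
  delays <- c(1, 15, 29, 94, 108, 122)
  prof <- data.frame(delay_days = delays,
                     a_star = 20 * (1 + 0.01 * delays), status = "ok")
  attr(prof, "ss_amount") <- 20
  class(prof) <- c("indifference_profile", class(prof))
  analytic <- stats::integrate(function(x) 1 / (1 + 0.01 * 122 * x),
                               0, 1)$value
  expect_lt(abs(auc(prof) - analytic) / analytic, 0.02)
})

test_that("AUC is invariant to rescaling all amounts", {
  rec <- hyperbolic_agent_records(log(0.02), seed = 24)
  a1 <- auc(indifference_points(rec))
  rec2 <- rec
  rec2$ss_amount <- rec$ss_amount * 3
  rec2$ll_amount <- rec$ll_amount * 3
  a2 <- auc(indifference_points(rec2))
  expect_equal(a1, a2, tolerance = 1e-10)
})

test_that("Friedman test matches base R on tie-free data and handles ties", {
  set.seed(25)
  m <- matrix(rnorm(34 * 3), 34, 3)
  ours <- friedman_test(m)
  ref <- stats::friedman.test(m)
  expect_equal(ours$chi2, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(ours$df, unname(ref$parameter))
  expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
  # perfectly consistent ranking: maximal statistic, tiny p
  m2 <- outer(rnorm(20), c(0, 1, 2), `+`)
  r2 <- friedman_test(m2)
  expect_equal(r2$chi2, 40)           # n*(k-1) at k=3
  expect_lt(r2$p, 1e-6)
  # row-constant matrix: statistic 0 under average-rank ties
  expect_equal(friedman_test(matrix(5, 10, 3))$chi2, 0)
  expect_error(friedman_test(matrix(c(1, NA, 2, 3, 4, 5), 2, 3)), "missing")
})

test_that("Friedman type-I error is near nominal under the null", {
  set.seed(26)
  rej <- mean(replicate(400, friedman_test(matrix(rnorm(34 * 3), 34, 3))$p < 0.05))
  expect_gt(rej, 0.02)
  expect_lt(rej, 0.09)
})

test_that("auc_table summarizes a small cohort", {
  cfg <- cohort_config(n_subjects = 4, model = "softmax", seed = 27)
  sim <- simulate_cohort(cfg)
  tab <- auc_table(sim$choices)
  expect_equal(nrow(tab), 12)
  expect_true(all(tab$auc >= 0 & tab$auc <= 1))
  expect_true(all(tab$n_usable_delays == 6))
})
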