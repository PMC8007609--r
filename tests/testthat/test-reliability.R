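test_that("ICC(A,k) equals the explicit variance-components oracle", {
  # oracle: mean squares from stats::aov on the long two-way layout
  icc_oracle <- function(m) {
    n <- nrow(m); k <- ncol(m)
    long <- data.frame(y = as.vector(m),
                       subj = factor(rep(seq_len(n), k)),
                       sess = factor(rep(seq_len(k), each = n)))
    ms <- summary(stats::aov(y ~ subj + sess, data = long))[[1]]$`Mean Sq`
    msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
    (msr - mse) / (msr + (msc - mse) / n)
  }
  set.seed(31)
  for (rep in 1:100) {
    n <- sample(5:40, 1); k <- sample(2:5, 1)
    m <- matrix(rnorm(n * k, sd = runif(1, 0.5, 3)), n, k) +
      rnorm(n, sd = runif(1, 0, 2))
    expect_equal(icc_agreement(m)$icc, icc_oracle(m), tolerance = 1e-10)
  }
})

test_that("ICC endpoints and category bands behave exactly", {
  x <- rnorm(20, sd = 2)
  res <- icc_agreement(cbind(x, x, x))
  expect_equal(res$icc, 1)
  expect_equal(res$category, "excellent")
  # zero total variance -> undefined
  expect_equal(icc_agreement(matrix(3, 10, 3))$category, "undefined")
  # iid noise -> centered at zero (the average-of-3 form is noisy per
  # draw, so the null check is distributional)
  set.seed(32)
  null_iccs <- replicate(200, icc_agreement(matrix(rnorm(34 * 3), 34, 3))$icc)
  expect_lt(abs(mean(null_iccs)), 0.1)
  expect_gt(mean(abs(null_iccs) < 0.6), 0.9)
  # half-open category boundaries at 0.5 / 0.75 / 0.9
  expect_equal(icc_category(0.4999), "poor")
  expect_equal(icc_category(0.5), "moderate")
  expect_equal(icc_category(0.7499), "moderate")
  expect_equal(icc_category(0.75), "good")
  expect_equal(icc_category(0.8999), "good")
  expect_equal(icc_category(0.9), "excellent")
  expect_equal(icc_category(-0.2), "poor")
  # CI brackets the estimate; p small for strong agreement
  set.seed(33)
  tr <- rnorm(34, sd = 2)
  m <- sapply(1:3, function(i) tr + rnorm(34, sd = 0.5))
  res <- icc_agreement(m)
  expect_lte(res$ci_low, res$icc)
  expect_gte(res$ci_high, res$icc)
  expect_lt(res$p, 0.001)
  expect_error(icc_agreement(matrix(rnorm(8), 4, 2)), "5 subjects")
})

test_that("trait/state cohorts land in the simulated ICC band", {
  # single-session reliability 0.7 at n = 34: the average-of-3 ICC of the
  # true per-session values concentrates in the brute-force band
  # [0.763, 0.930] (2.5%-97.5% quantiles from a 2000-rep simulation of the
  # same generative model; Spearman-Brown lifts the single-measure 0.7 to
  # a median near 0.87)
  set.seed(34)
  iccs <- replicate(60, {
    tr <- rnorm(34, 0, sqrt(0.7))
    m <- sapply(1:3, function(i) tr + rnorm(34, 0, sqrt(0.3)))
    icc_agreement(m)$icc
  })
  expect_gt(mean(iccs > 0.763 & iccs < 0.930), 0.85)
  expect_lt(abs(median(iccs) - 0.874), 0.05)
})

test_that("pairwise session correlations hit their algebraic anchors", {
  x <- rnorm(20)
  expect_equal(unname(pairwise_session_correlations(cbind(x, x, x))),
               c(1, 1, 1))
  r <- pairwise_session_correlations(cbind(x, -x, x))
  expect_equal(unname(r), c(-1, 1, -1))
  expect_error(pairwise_session_correlations(cbind(x[1:2], x[1:2], x[1:2])),
               "3 subjects")
})

test_that("split-half refits: degenerate identical halves correlate near 1", {
  # duplicate every trial at consecutive indices so the odd and even
  # halves contain identical data
  cfg <- cohort_config(n_subjects = 8, model = "softmax", seed = 35)
  sim <- simulate_cohort(cfg)
  d <- sim$choices[sim$choices$session == "lab", ]
  prep <- lapply(split(d, d$subject_id), function(rec) {
    rec2 <- rec[rep(seq_len(48), each = 2), ]
    rec2$trial_index <- seq_len(96) - 1L
    preprocess_rts(rec2, trim_fraction = 0)
  })
  sh <- split_half(prep, "softmax", mcmc = fast_mcmc(seed = 6))
  expect_equal(nrow(sh$estimates$odd), 8)
  r_logk <- sh$reliability$pearson_r[sh$reliability$parameter == "log_k"]
  expect_gt(r_logk, 0.95)
  # conservation of the partition
  one <- prep[[1]]$records
  expect_equal(sum(one$trial_index %% 2 == 0) +
                 sum(one$trial_index %% 2 == 1), nrow(one))
})
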