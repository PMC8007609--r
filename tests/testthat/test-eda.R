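test_that("binning and baseline normalization are exact on designed input", {
  t <- 0:899
  rec <- data.frame(subject_id = "S01", session = "vr_neutral",
                    time_s = t, scl_uS = 5,
                    scr_event = as.integer(t %% 60 == 0),
                    phase = rep(c("B", "F", "S"), each = 300))
  pb <- bin_and_normalize(rec)
  expect_equal(nrow(pb), 15)
  expect_equal(pb$scl_pct, rep(0, 15))        # constant signal -> 0%
  expect_equal(pb$nscr_pct, rep(0, 15))       # constant rate -> 0%
  expect_equal(sum(pb$nscr), sum(rec$scr_event))  # event conservation
  # doubling at VR entry -> +100% in F and S bins
  rec2 <- rec
  rec2$scl_uS <- ifelse(t >= 300, 10, 5)
  pb2 <- bin_and_normalize(rec2)
  expect_equal(pb2$scl_pct[1:5], rep(0, 5))
  expect_equal(pb2$scl_pct[6:15], rep(100, 10))
  # invariance to rescaling the raw signal
  rec3 <- rec2
  rec3$scl_uS <- rec3$scl_uS * 7.3
  expect_equal(bin_and_normalize(rec3)$scl_pct, pb2$scl_pct)
})

test_that("partial bins and empty baselines are refused", {
  t <- 0:899
  rec <- data.frame(subject_id = "S01", session = "vr_neutral",
                    time_s = t, scl_uS = 5,
                    scr_event = 0L,
                    phase = rep(c("B", "F", "S"), each = 300))
  short <- rec[rec$time_s < 850, ]            # S phase cut at 250 s
  expect_error(bin_and_normalize(short), "partial final bin")
  rec0 <- rec
  rec0$scl_uS <- 0
  expect_error(bin_and_normalize(rec0), "baseline SCL")
})

test_that("Wilcoxon effect size reproduces the worked values", {
  expect_equal(round(wilcoxon_effect_r(-3.67, 26), 2), 0.72)
  expect_equal(round(wilcoxon_effect_r(-3.543, 26), 3), 0.695)
  expect_equal(effect_size_band(0.72), "large")
  expect_equal(effect_size_band(0.346), "medium")
  expect_equal(effect_size_band(0.1), "small")
})

test_that("Wilcoxon z, p and exact small-n path agree with base R", {
  set.seed(61)
  # large-n: normal approximation with tie correction
  x <- rnorm(30); y <- x + rnorm(30, 0.5)
  ours <- wilcoxon_r(x, y)
  ref <- stats::wilcox.test(x, y, paired = TRUE, exact = FALSE,
                            correct = FALSE)
  expect_equal(ours$p, ref$p.value, tolerance = 1e-10)
  expect_equal(ours$r, abs(ours$z) / sqrt(30))
  # small-n tie-free: exact enumeration matches the exact wilcox.test
  x2 <- c(1.3, 2.1, 0.4, -0.7, 1.9, 2.6, -1.2, 0.9)
  y2 <- x2 - c(0.71, 0.93, -0.62, -0.88, 1.14, 0.69, -1.53, -0.47)
  ours2 <- wilcoxon_r(x2, y2)
  ref2 <- stats::wilcox.test(x2, y2, paired = TRUE, exact = TRUE)
  expect_equal(ours2$p, ref2$p.value, tolerance = 1e-12)
  # identical vectors: undefined, reported
  res0 <- wilcoxon_r(x, x)
  expect_true(is.na(res0$z))
  expect_equal(res0$n_zero, 30)
  expect_error(wilcoxon_r(1:3, 4:6), "6 pairs")
})

test_that("phase contrasts detect a designed tonic step and nothing else", {
  eda <- rbind(
    simulate_eda(n_subjects = 26, vr_step = 0.3, drift_per_min = 0,
                 session = "vr_neutral", seed = 62),
    simulate_eda(n_subjects = 26, vr_step = 0.3, drift_per_min = 0,
                 session = "vr_gambling", seed = 63))
  ctr <- phase_contrasts(bin_eda_table(eda))
  scl <- ctr[ctr$measure == "scl_pct", ]
  entry <- scl[scl$contrast == "B5_vs_F1", ]
  expect_true(all(entry$p < 0.05))            # step at VR entry detected
  expect_true(all(entry$r > 0.5))             # large effect
  inner <- scl[scl$contrast == "F5_vs_S1", ]
  expect_true(all(inner$p > 0.05))            # no second step
  across <- scl[scl$contrast == "F5S1_across_sessions", ]
  expect_true(across$p > 0.05)                # environments identical
})

test_that("null EDA generator keeps the false-positive rate near nominal", {
  set.seed(64)
  ps <- replicate(10, {
    eda <- rbind(
      simulate_eda(n_subjects = 10, vr_step = 0, drift_per_min = 0,
                   phasic_rate_vr = 4, session = "vr_neutral",
                   seed = sample.int(1e6, 1)),
      simulate_eda(n_subjects = 10, vr_step = 0, drift_per_min = 0,
                   phasic_rate_vr = 4, session = "vr_gambling",
                   seed = sample.int(1e6, 1)))
    ctr <- phase_contrasts(bin_eda_table(eda))
    mean(ctr$p < 0.05, na.rm = TRUE)
  })
  expect_lt(mean(ps), 0.15)
})

test_that("a single subject is refused", {
  eda <- simulate_eda(n_subjects = 1, seed = 65)
  expect_error(phase_contrasts(bin_eda_table(eda)), "too few")
})
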