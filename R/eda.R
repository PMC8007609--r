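#' Phase-binned, baseline-normalized electrodermal summaries
#'
#' For one subject-session recording: each of the three 5-minute phases
#' (B = baseline, F = first exploration, S = second exploration) is cut
#' into five one-minute bins. Per bin, the tonic measure is the mean skin
#' conductance level and the phasic measure the count of spontaneous SCR
#' events. Both are converted to percent change from the baseline-phase
#' mean of the raw measure: 100 * (value - baseline_mean) / baseline_mean,
#' where baseline_mean averages bins B1-B5.
#'
#' @param recording Data frame in the EDA schema for one subject-session.
#' @return A `phase_bins` data frame: bin (B1..S5), scl_pct, nscr_pct, plus
#'   raw bin values.
#' @export
bin_and_normalize <- function(recording) {
  stopifnot(nrow(recording) > 0)
  if (length(unique(recording$subject_id)) > 1 ||
      length(unique(recording$session)) > 1)
    stop("bin_and_normalize expects a single subject-session")
  labels <- paste0(rep(c("B", "F", "S"), each = 5), 1:5)
  bins <- lapply(c("B", "F", "S"), function(ph) {
    d <- recording[recording$phase == ph, ]
    if (nrow(d) == 0) stop("phase ", ph, " missing")
    t0 <- min(d$time_s)
    idx <- floor((d$time_s - t0) / 60)
    if (max(d$time_s) - t0 < 300 - 1.5)
      stop("phase ", ph, " has a partial final bin (< 60 s)")
    idx[idx > 4] <- 4
    data.frame(bin = paste0(ph, 1:5),
               scl = as.vector(tapply(d$scl_uS, factor(idx, 0:4), mean)),
               nscr = as.vector(tapply(d$scr_event, factor(idx, 0:4), sum)))
  })
  out <- do.call(rbind, bins)
  base_scl <- mean(out$scl[1:5])
  base_nscr <- mean(out$nscr[1:5])
  if (base_scl <= 0) stop("baseline SCL mean must be positive")
  if (base_nscr <= 0) stop("baseline SCR count mean must be positive")
  out$scl_pct <- 100 * (out$scl - base_scl) / base_scl
  out$nscr_pct <- 100 * (out$nscr - base_nscr) / base_nscr
  out$bin <- factor(out$bin, levels = labels)
  rownames(out) <- NULL
  class(out) <- c("phase_bins", class(out))
  out
}

#' Wilcoxon signed-rank test with effect size r = |Z| / sqrt(N)
#'
#' Paired signed-rank test: zero differences are dropped (their count is
#' reported), ranks of |differences| use midranks, and the standardized
#' statistic Z uses the tie-corrected normal approximation. Below 12
#' non-zero pairs without ties the exact signed-rank distribution
#' (`psignrank`) supplies the p-value instead. The effect size is
#' r = |Z| / sqrt(N) with N the number of pairs entered (before zero
#' removal), with the usual bands: small < 0.3, medium 0.3-0.5,
#' large > 0.5.
#'
#' @param x,y Paired measurements (>= 6 pairs).
#' @return List with `z`, `p`, `r`, `n` (pairs entered), `n_zero` (dropped),
#'   `band`. All-zero differences give `z = NA` (undefined), reported as
#'   such.
#' @export
wilcoxon_r <- function(x, y) {
  stopifnot(length(x) == length(y))
  n_in <- length(x)
  if (n_in < 6) stop("at least 6 pairs are required")
  d <- x - y
  n_zero <- sum(d == 0)
  d <- d[d != 0]
  if (length(d) == 0)
    return(list(z = NA_real_, p = NA_real_, r = NA_real_, n = n_in,
                n_zero = n_zero, band = "undefined"))
  nr <- length(d)
  rk <- rank(abs(d))
  w_pos <- sum(rk[d > 0])
  mu <- nr * (nr + 1) / 4
  ties <- table(rk)
  tie_corr <- sum(ties^3 - ties) / 48
  sigma <- sqrt(nr * (nr + 1) * (2 * nr + 1) / 24 - tie_corr)
  z <- if (sigma > 0) (w_pos - mu) / sigma else NA_real_
  has_ties <- any(ties > 1)
  if (nr < 12 && !has_ties) {
    # exact two-sided p by enumeration of the signed-rank distribution
    p <- 2 * min(stats::psignrank(w_pos, nr),
                 stats::psignrank(nr * (nr + 1) / 2 - w_pos, nr))
    p <- min(p, 1)
  } else {
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(z = z, p = p, r = wilcoxon_effect_r(z, n_in), n = n_in,
       n_zero = n_zero, band = effect_size_band(wilcoxon_effect_r(z, n_in)))
}

#' @rdname wilcoxon_r
#' @param z Standardized Wilcoxon statistic.
#' @param n Number of pairs entered.
#' @export
wilcoxon_effect_r <- function(z, n) abs(z) / sqrt(n)

#' @rdname wilcoxon_r
#' @param r Effect size.
#' @export
effect_size_band <- function(r) {
  if (is.na(r)) return("undefined")
  if (r < 0.3) "small" else if (r <= 0.5) "medium" else "large"
}

#' The four phase contrasts on binned EDA measures
#'
#' Given `phase_bins` for all subjects of the two VR sessions, evaluates,
#' for each measure (SCL percent change, nSCR percent change):
#' B5 vs F1 within each VR session (did VR entry raise arousal), F5 vs S1
#' within each session (did entering the experimental area raise it
#' further), and the across-session comparison of the per-subject F5 - S1
#' difference scores (did the two environments differ). Subjects missing a
#' complete set of bins in a session are dropped and logged.
#'
#' @param bins_by_subject Named list: for each session label, a list of
#'   `phase_bins` indexed by subject.
#' @return Data frame: measure, contrast, session, z, p, r, n, band.
#' @export
phase_contrasts <- function(bins_by_subject) {
  sessions <- names(bins_by_subject)
  stopifnot(length(sessions) >= 1)
  get_bin <- function(pb, bin, col) pb[[col]][pb$bin == bin]
  out <- list()
  for (meas in c("scl_pct", "nscr_pct")) {
    f5s1 <- list()
    for (ses in sessions) {
      pbs <- bins_by_subject[[ses]]
      complete <- vapply(pbs, function(pb) nrow(pb) == 15, TRUE)
      if (any(!complete))
        message(sum(!complete), " subject(s) dropped in ", ses,
                " (incomplete bins)")
      pbs <- pbs[complete]
      if (length(pbs) < 2) stop("too few complete subjects in ", ses)
      b5 <- vapply(pbs, get_bin, 0, "B5", meas)
      f1 <- vapply(pbs, get_bin, 0, "F1", meas)
      f5 <- vapply(pbs, get_bin, 0, "F5", meas)
      s1 <- vapply(pbs, get_bin, 0, "S1", meas)
      w1 <- wilcoxon_r(b5, f1)
      w2 <- wilcoxon_r(f5, s1)
      f5s1[[ses]] <- f5 - s1
      out[[length(out) + 1]] <- data.frame(
        measure = meas, contrast = "B5_vs_F1", session = ses,
        z = w1$z, p = w1$p, r = w1$r, n = w1$n, band = w1$band)
      out[[length(out) + 1]] <- data.frame(
        measure = meas, contrast = "F5_vs_S1", session = ses,
        z = w2$z, p = w2$p, r = w2$r, n = w2$n, band = w2$band)
    }
    if (length(sessions) == 2) {
      w3 <- wilcoxon_r(f5s1[[1]], f5s1[[2]])
      out[[length(out) + 1]] <- data.frame(
        measure = meas, contrast = "F5S1_across_sessions",
        session = paste(sessions, collapse = "-"),
        z = w3$z, p = w3$p, r = w3$r, n = w3$n, band = w3$band)
    }
  }
  do.call(rbind, out)
}

#' Bin all subjects of an EDA table
#'
#' @param eda EDA table (possibly several subjects/sessions).
#' @return Named list by session of lists of `phase_bins` by subject.
#' @export
bin_eda_table <- function(eda) {
  out <- list()
  for (ses in unique(eda$session)) {
    d <- eda[eda$session == ses, ]
    out[[ses]] <- lapply(split(d, d$subject_id), bin_and_normalize)
  }
  out
}
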