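#' Intraclass correlation: two-way model, absolute agreement, average of k
#'
#' McGraw-Wong ICC(A,k) for a complete subjects x sessions matrix, computed
#' from the two-way ANOVA mean squares: ICC = (MSR - MSE) / (MSR +
#' (MSC - MSE) / n). The 95 percent confidence interval follows the
#' McGraw-Wong construction for single-rater agreement with a
#' Satterthwaite-approximated denominator df, transformed to the average-of-k
#' form by Spearman-Brown; the p-value is from F = MSR / MSE with
#' (n - 1, (n - 1)(k - 1)) df. Reliability categories use half-open bands:
#' [0, 0.5) poor, [0.5, 0.75) moderate, [0.75, 0.9) good, [0.9, 1]
#' excellent (negative estimates fall in `poor`).
#'
#' @param m Numeric matrix, n subjects (>= 5) x k sessions (>= 2), complete.
#' @param conf Confidence level for the interval.
#' @return An `icc_result` list: `icc`, `ci_low`, `ci_high`, `p`,
#'   `category`, plus the mean squares. If the matrix has zero total
#'   variance the ICC is undefined and returned as `NA` with category
#'   `"undefined"`.
#' @export
icc_agreement <- function(m, conf = 0.95) {
  m <- as.matrix(m)
  n <- nrow(m); k <- ncol(m)
  if (n < 5) stop("at least 5 subjects are required")
  if (k < 2) stop("at least 2 sessions are required")
  if (anyNA(m)) stop("missing cells are not allowed")

  if (stats::var(as.vector(m)) == 0)
    return(structure(list(icc = NA_real_, ci_low = NA_real_,
                          ci_high = NA_real_, p = NA_real_,
                          category = "undefined",
                          msr = 0, msc = 0, mse = 0, n = n, k = k),
                     class = "icc_result"))

  g <- mean(m)
  msr <- k * sum((rowMeans(m) - g)^2) / (n - 1)
  msc <- n * sum((colMeans(m) - g)^2) / (k - 1)
  sse <- sum((m - g)^2) - (n - 1) * msr - (k - 1) * msc
  mse <- sse / ((n - 1) * (k - 1))

  icc_k <- (msr - mse) / (msr + (msc - mse) / n)

  # CI: single-measure agreement bounds, then Spearman-Brown to k measures
  icc_1 <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  alpha <- 1 - conf
  a <- (k * icc_1) / (n * (1 - icc_1))
  b <- 1 + (k * icc_1 * (n - 1)) / (n * (1 - icc_1))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  f_l <- stats::qf(1 - alpha / 2, n - 1, v)
  f_u <- stats::qf(1 - alpha / 2, v, n - 1)
  l1 <- n * (msr - f_l * mse) /
    (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
  u1 <- n * (f_u * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f_u * msr)
  sb <- function(r) r * k / (1 + (k - 1) * r)
  ci <- sort(c(sb(l1), sb(u1)))

  p <- stats::pf(msr / mse, n - 1, (n - 1) * (k - 1), lower.tail = FALSE)

  structure(list(icc = icc_k, ci_low = ci[1], ci_high = ci[2], p = p,
                 category = icc_category(icc_k),
                 msr = msr, msc = msc, mse = mse, n = n, k = k),
            class = "icc_result")
}

#' @rdname icc_agreement
#' @param icc ICC value.
#' @export
icc_category <- function(icc) {
  if (is.na(icc)) return("undefined")
  if (icc < 0.5) "poor"
  else if (icc < 0.75) "moderate"
  else if (icc < 0.9) "good"
  else "excellent"
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC(A,%d) = %.3f [%.3f, %.3f], p = %.3g (%s)\n",
              x$k, x$icc, x$ci_low, x$ci_high, x$p, x$category))
  invisible(x)
}

#' Within-session split-half reliability by refitting
#'
#' Splits every subject's retained trials into odd and even trials (parity
#' of `trial_index`), fits the model hierarchically and independently to
#' each half, and computes between-half reliability of the subject-level
#' posterior means per parameter (Pearson r and ICC(A,2)). A half flagged
#' as non-converged is recorded in `notes` but still reported.
#'
#' @param prepared List of `prepared_session` objects (one per subject).
#' @param model Model name.
#' @param mcmc MCMC settings passed to [fit_hierarchical()].
#' @return List with `estimates` (subject x parameter posterior means for
#'   both halves), `reliability` (per-parameter r and ICC), the two fits,
#'   and `notes`.
#' @export
split_half <- function(prepared, model, mcmc = list()) {
  halves <- lapply(c(0, 1), function(par) {
    lapply(prepared, function(p) {
      rec <- p$records[p$records$trial_index %% 2 == par, , drop = FALSE]
      if (nrow(rec) < 20)
        stop("fewer than 20 trials in one half for subject ",
             rec$subject_id[1])
      structure(list(records = rec, n_trimmed = 0L),
                class = "prepared_session")
    })
  })
  notes <- character()
  fits <- lapply(seq_along(halves), function(h) {
    f <- withCallingHandlers(
      fit_hierarchical(model, halves[[h]], mcmc = mcmc),
      warning = function(w) {
        notes <<- c(notes, sprintf("half %d: %s", h, conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
    f
  })
  pn <- model_params(model)
  est <- lapply(fits, subject_posterior_means)
  rel <- do.call(rbind, lapply(pn, function(p) {
    x <- est[[1]][, p]; y <- est[[2]][, p]
    icc <- icc_agreement(cbind(x, y))
    data.frame(parameter = p, pearson_r = stats::cor(x, y), icc = icc$icc,
               icc_category = icc$category)
  }))
  list(estimates = list(odd = est[[1]], even = est[[2]]),
       reliability = rel, fits = fits, notes = notes)
}

#' Pairwise Pearson correlations of subject estimates between sessions
#'
#' @param est Matrix or data frame, subjects x 3 sessions (columns ordered
#'   lab, vr_neutral, vr_gambling), complete cases only.
#' @return Named vector of 3 correlations (lab-vrN, lab-vrG, vrN-vrG).
#' @export
pairwise_session_correlations <- function(est) {
  est <- as.matrix(est)
  stopifnot(ncol(est) == 3)
  if (nrow(est) < 3) stop("at least 3 subjects are required")
  c(lab_vr_neutral = stats::cor(est[, 1], est[, 2]),
    lab_vr_gambling = stats::cor(est[, 1], est[, 3]),
    vr_neutral_vr_gambling = stats::cor(est[, 2], est[, 3]))
}
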