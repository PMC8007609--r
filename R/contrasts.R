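#' Posterior difference distribution between two independently fit sessions
#'
#' The two sample sets are thinned to the shorter common length, one side is
#' randomly permuted (seeded) to make the pairing explicitly exchangeable,
#' and the elementwise difference a - b is returned. Any exchangeable
#' pairing yields the same marginal difference distribution; the permutation
#' just removes accidental within-chain coupling.
#'
#' @param samples_a,samples_b Posterior draws of the same group-level
#'   parameter from two independent fits.
#' @param seed Integer seed for the pairing permutation.
#' @return Numeric vector of difference samples.
#' @export
difference_distribution <- function(samples_a, samples_b, seed = 1L) {
  n <- min(length(samples_a), length(samples_b))
  if (n < 1000)
    warning("fewer than 1000 samples; directional BF will be unstable")
  a <- samples_a[seq_len(n)]
  b <- samples_b[seq_len(n)]
  set.seed(as.integer(seed))
  a - b[sample.int(n)]
}

#' Highest density interval of a sample
#'
#' Narrowest contiguous interval containing the requested probability mass
#' (sorted-window method).
#'
#' @param samples Numeric vector (>= 100 values).
#' @param mass Interval mass in (0, 1).
#' @return Numeric vector `c(low, high)`.
#' @export
hdi <- function(samples, mass = 0.95) {
  if (mass <= 0 || mass >= 1) stop("mass must be in (0, 1)")
  if (length(samples) < 100) stop("at least 100 samples are required")
  x <- sort(samples)
  n <- length(x)
  k <- max(1, ceiling(mass * n))
  if (k >= n) return(c(x[1], x[n]))
  widths <- x[(k + 1):n] - x[1:(n - k)]
  i <- which.min(widths)
  c(x[i], x[i + k])
}

#' Directional Bayes factor from a difference distribution
#'
#' dBF = (mass above zero) / (mass below zero); samples exactly at zero are
#' excluded. If one side is empty its count is floored at one sample and
#' the result flagged as a bound. Interpretation bands follow the usual
#' convention: dBF >= 3 moderate, >= 12 strong, > 100 extreme evidence for
#' a positive shift; the reciprocal bands (<= 1/3 etc.) for a negative
#' shift.
#'
#' @param diff_samples Difference samples (>= 1000 recommended).
#' @return List with `dbf`, `i` (mass above zero), `bound` (TRUE when one
#'   side was empty), `band`.
#' @export
directional_bf <- function(diff_samples) {
  pos <- sum(diff_samples > 0)
  neg <- sum(diff_samples < 0)
  bound <- FALSE
  if (pos == 0) { pos <- 1; bound <- TRUE }
  if (neg == 0) { neg <- 1; bound <- TRUE }
  dbf <- pos / neg
  band <- if (dbf > 100) "extreme (positive)"
  else if (dbf >= 12) "strong (positive)"
  else if (dbf >= 3) "moderate (positive)"
  else if (dbf < 1 / 100) "extreme (negative)"
  else if (dbf <= 1 / 12) "strong (negative)"
  else if (dbf <= 1 / 3) "moderate (negative)"
  else "inconclusive"
  list(dbf = dbf, i = pos / (pos + neg), bound = bound, band = band)
}

#' Cohen's d and between-session correlation for paired subject estimates
#'
#' d = (mean_a - mean_b) / sqrt((sd_a^2 + sd_b^2) / 2) (root-mean pooled
#' SD); the Pearson correlation of the pairs is computed and reported
#' alongside but not folded into d.
#'
#' @param a,b Paired subject-level estimates (complete subjects).
#' @return List with `d`, `r_sessions`, `n`.
#' @export
cohens_d <- function(a, b) {
  stopifnot(length(a) == length(b))
  ok <- stats::complete.cases(a, b)
  a <- a[ok]; b <- b[ok]
  pooled <- sqrt((stats::var(a) + stats::var(b)) / 2)
  if (!is.finite(pooled) || pooled == 0)
    return(list(d = NA_real_, r_sessions = suppressWarnings(stats::cor(a, b)),
                n = length(a)))
  list(d = (mean(a) - mean(b)) / pooled,
       r_sessions = stats::cor(a, b), n = length(a))
}

#' Session-contrast table for a fitted model
#'
#' For every parameter of the model and every session pair, computes the
#' group-mean posterior difference distribution, its mean and 95 percent
#' HDI, the directional Bayes factor, and Cohen's d with the
#' between-session correlation of the subject-level posterior means.
#'
#' @param fits Named list of `hier_fit` objects (same model), e.g.
#'   `list(lab = ..., vr_neutral = ..., vr_gambling = ...)`.
#' @param seed Seed for the pairing permutations.
#' @return Data frame: parameter, pair, mean_diff, hdi_low, hdi_high, dbf,
#'   dbf_band, d, r_sessions.
#' @export
session_contrasts <- function(fits, seed = 1L) {
  stopifnot(length(fits) >= 2)
  model <- unique(vapply(fits, function(f) f$model, ""))
  if (length(model) > 1) stop("fits must share a model")
  pn <- model_params(model)
  nm <- names(fits)
  pairs <- utils::combn(length(fits), 2)
  means <- lapply(fits, subject_posterior_means)
  out <- list()
  for (p in pn) {
    for (j in seq_len(ncol(pairs))) {
      i1 <- pairs[1, j]; i2 <- pairs[2, j]
      dd <- difference_distribution(group_mean_draws(fits[[i1]], p),
                                    group_mean_draws(fits[[i2]], p),
                                    seed = seed + j)
      h <- hdi(dd)
      bf <- directional_bf(dd)
      cd <- cohens_d(means[[i1]][, p], means[[i2]][, p])
      out[[length(out) + 1]] <- data.frame(
        parameter = p, pair = paste(nm[i1], nm[i2], sep = "-"),
        mean_diff = mean(dd), hdi_low = h[1], hdi_high = h[2],
        dbf = bf$dbf, dbf_band = bf$band, d = cd$d,
        r_sessions = cd$r_sessions)
    }
  }
  do.call(rbind, out)
}
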