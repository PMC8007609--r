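#' Per-delay indifference points from logistic fits
#'
#' For each delay of one subject-session, P(choice = LL) is fit as a
#' logistic function of the LL amount by maximum likelihood and the
#' indifference point A* (the LL amount at which the choice probability is
#' 0.5) is read off as -b0/b1. A* is clamped to the offer range
#' [20, 77] Euros (77 = 20 x 3.85). Degenerate fits are handled by rule:
#' with perfect separation, A* is the midpoint between the largest
#' always-LL amount and the smallest always-SS amount when both exist and
#' the range boundary otherwise; a non-positive fitted slope
#' (noise-dominated responding) falls back to the same midpoint rule and is
#' flagged. Delays with fewer than two distinct LL amounts are marked
#' unusable.
#'
#' @param records One subject-session's choice records.
#' @return An `indifference_profile`: data frame (delay_days, a_star,
#'   status) sorted by delay, with `status` one of `ok`, `separated`,
#'   `flat`, `unusable`.
#' @export
indifference_points <- function(records) {
  ss <- records$ss_amount[1]
  amax <- ss * 3.85
  prof <- lapply(split(records, records$delay_days), function(d) {
    amounts <- d$ll_amount
    if (length(unique(amounts)) < 2)
      return(data.frame(delay_days = d$delay_days[1], a_star = NA_real_,
                        status = "unusable"))
    # separation midpoint: largest amount always answered SS below it,
    # smallest amount always answered LL above it
    agg <- tapply(d$choice, amounts, mean)
    av <- as.numeric(names(agg))
    midpoint <- function() {
      top_ss <- suppressWarnings(max(av[agg == 0]))   # always-SS amounts
      bot_ll <- suppressWarnings(min(av[agg == 1]))   # always-LL amounts
      if (is.finite(top_ss) && is.finite(bot_ll)) (top_ss + bot_ll) / 2
      else if (is.finite(bot_ll)) ss                  # all-LL responder
      else if (is.finite(top_ss)) amax                # all-SS responder
      else mean(range(av))
    }
    sep <- all(agg %in% c(0, 1))
    if (sep) {
      astar <- midpoint()
      status <- "separated"
    } else {
      fit <- suppressWarnings(
        stats::glm(choice ~ ll_amount, family = stats::binomial(), data = d))
      b <- stats::coef(fit)
      if (!all(is.finite(b)) || b[2] <= 0) {
        astar <- midpoint()
        status <- "flat"
      } else {
        astar <- -b[1] / b[2]
        status <- "ok"
      }
    }
    data.frame(delay_days = d$delay_days[1],
               a_star = min(max(astar, ss), amax), status = status)
  })
  out <- do.call(rbind, prof)
  out <- out[order(out$delay_days), ]
  rownames(out) <- NULL
  attr(out, "ss_amount") <- ss
  class(out) <- c("indifference_profile", class(out))
  out
}

#' Normalized area under the indifference curve
#'
#' Delays are normalized as x = delay / max_delay and indifference points
#' converted to relative subjective value y = ss / A* (1 = no discounting,
#' about 0.26 at the steepest measurable discounting). The anchor (0, 1) is
#' prepended, the curve integrated by the trapezoid rule over sorted x, and
#' the area divided by the x-range covered, giving AUC in [0, 1].
#'
#' @param profile An `indifference_profile` (unusable delays are skipped).
#' @param max_delay Normalizing delay (days).
#' @return Scalar AUC.
#' @export
auc <- function(profile, max_delay = 122) {
  ss <- attr(profile, "ss_amount")
  if (is.null(ss)) ss <- 20
  use <- profile[!is.na(profile$a_star), , drop = FALSE]
  if (nrow(use) == 0) stop("no usable delays; AUC undefined")
  x <- c(0, use$delay_days / max_delay)
  y <- c(1, ss / use$a_star)
  o <- order(x)
  x <- x[o]; y <- y[o]
  area <- sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  area / (max(x) - min(x))
}

#' Friedman rank test across the three sessions
#'
#' Tie-corrected Friedman statistic (Conover form) for a complete
#' subjects x sessions matrix: within-row average ranks, chi-squared
#' statistic (k-1) * (sum_j R_j^2 - n^2 k (k+1)^2 / 4) / (A1 - C1) with
#' A1 the sum of squared ranks and C1 = n k (k+1)^2 / 4, df = k - 1. A
#' matrix in which every row is constant has zero rank variance; the
#' statistic is reported as 0 with p = 1.
#'
#' @param m Numeric matrix, subjects x sessions, no missing cells.
#' @return List with `chi2`, `df`, `p`.
#' @export
friedman_test <- function(m) {
  m <- as.matrix(m)
  if (anyNA(m)) stop("missing cells are not allowed")
  n <- nrow(m); k <- ncol(m)
  if (n < 3) stop("at least 3 subjects are required")
  r <- t(apply(m, 1, rank))
  rj <- colSums(r)
  a1 <- sum(r^2)
  c1 <- n * k * (k + 1)^2 / 4
  denom <- a1 - c1
  if (denom <= 0) return(list(chi2 = 0, df = k - 1, p = 1))
  chi2 <- (k - 1) * (sum(rj^2) - n^2 * k * (k + 1)^2 / 4) / denom
  list(chi2 = chi2, df = k - 1,
       p = stats::pchisq(chi2, k - 1, lower.tail = FALSE))
}

#' Model-free AUC table for a whole cohort
#'
#' Convenience wrapper: indifference points and AUC per subject-session.
#'
#' @param choices Trial-level table (all subjects and sessions).
#' @return Data frame subject_id, session, auc, n_usable_delays.
#' @export
auc_table <- function(choices) {
  keys <- unique(choices[, c("subject_id", "session")])
  out <- lapply(seq_len(nrow(keys)), function(i) {
    rec <- choices[choices$subject_id == keys$subject_id[i] &
                     choices$session == keys$session[i], ]
    prof <- indifference_points(rec)
    data.frame(subject_id = keys$subject_id[i], session = keys$session[i],
               auc = auc(prof),
               n_usable_delays = sum(!is.na(prof$a_star)))
  })
  do.call(rbind, out)
}
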