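#' Construct the three mean-matched trial sets
#'
#' The task crosses 6 delays with 16 larger-later (LL) multiples of the fixed
#' 20 Euro smaller-sooner reward, giving 96 trials per set; three such sets
#' are used, one per session, and must have identical mean delay and mean LL
#' amount. The constructor lays an 18-value integer delay grid on [1, 122]
#' and a 48-value arithmetic multiple grid on [1.025, 3.85], forms symmetric
#' pairs around each grid's midpoint (every delay pair sums to 123, every
#' multiple pair to 4.875), and deals whole pairs to the three sets - 3 delay
#' pairs and 8 multiple pairs per set - so the set means are equal by
#' construction. The seed permutes which pairs land in which set.
#'
#' @param seed Integer seed governing the pair-to-set assignment.
#' @param tolerance Maximum relative difference allowed between set means
#'   (verified, not used to steer construction).
#' @return List of 3 `trial_set` lists with fields `set_id`, `delays`,
#'   `ll_multiples`, `trials` (96-row data frame of `delay_days`,
#'   `ll_amount`).
#' @export
build_trial_sets <- function(seed = 1L, tolerance = 1e-6) {
  # 9 symmetric integer delay pairs spanning 1..122 (step 7 on the low arm)
  lo <- seq(1, 57, by = 7)
  delay_pairs <- cbind(lo, 123 - lo)
  # 24 symmetric multiple pairs on an arithmetic 48-grid over [1.025, 3.85]
  mgrid <- seq(1.025, 3.85, length.out = 48)
  mult_pairs <- cbind(mgrid[1:24], rev(mgrid)[1:24])

  set.seed(as.integer(seed) %% .Machine$integer.max)
  # stratified dealing: pairs are ordered from outermost to innermost, and
  # every set receives one pair per stratum of three consecutive pairs, so
  # each set's values stay spread over the whole range (a set of clustered
  # delays could not resolve mid-range discounting); the seed permutes the
  # within-stratum assignment
  deal <- function(n_pairs) {
    out <- integer(n_pairs)
    for (s in seq_len(n_pairs / 3))
      out[(s - 1) * 3 + 1:3] <- sample.int(3)
    out
  }
  dp_set <- deal(9)
  mp_set <- deal(24)

  sets <- lapply(1:3, function(s) {
    delays <- sort(as.vector(delay_pairs[dp_set == s, ]))
    mults <- sort(as.vector(mult_pairs[mp_set == s, ]))
    trials <- expand.grid(delay_days = delays, ll_amount = 20 * mults,
                          KEEP.OUT.ATTRS = FALSE)
    structure(list(set_id = s - 1L, delays = delays, ll_multiples = mults,
                   trials = trials),
              class = "trial_set")
  })

  mean_d <- vapply(sets, function(s) mean(s$trials$delay_days), 0)
  mean_a <- vapply(sets, function(s) mean(s$trials$ll_amount), 0)
  rel <- function(x) diff(range(x)) / max(abs(x))
  if (rel(mean_d) > tolerance || rel(mean_a) > tolerance)
    stop(sprintf(paste0("trial-set means not matched: delays %s, ",
                        "amounts %s"),
                 paste(signif(mean_d, 10), collapse = "/"),
                 paste(signif(mean_a, 10), collapse = "/")))
  sets
}

#' Counterbalanced set-to-session assignment and presentation order
#'
#' Assigns each subject one trial set per session following a Latin square
#' over subjects (subject i, session j receives set (i + j) mod 3 under a
#' seeded relabelling), so every subject sees every set exactly once and
#' sets are balanced across sessions. Trial order within a session is an
#' independent seeded permutation per subject-session.
#'
#' @param sets Trial sets from [build_trial_sets()].
#' @param n_subjects Number of subjects.
#' @param seed Integer seed.
#' @return Data frame with columns `subject`, `session`, `set_id` plus a
#'   list-column `order` holding the within-session trial permutation.
#' @export
shuffle_presentation <- function(sets, n_subjects, seed = 1L) {
  stopifnot(length(sets) == 3, n_subjects >= 1)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  relabel <- sample.int(3)               # seeded Latin-square relabelling
  out <- expand.grid(subject = seq_len(n_subjects), session = 1:3,
                     KEEP.OUT.ATTRS = FALSE)
  out <- out[order(out$subject, out$session), ]
  out$set_id <- relabel[((out$subject - 1) + (out$session - 1)) %% 3 + 1] - 1L
  out$order <- lapply(seq_len(nrow(out)), function(i)
    sample.int(nrow(sets[[out$set_id[i] + 1L]]$trials)))
  rownames(out) <- NULL
  out
}

#' Write trial sets to CSV
#'
#' Columns `set_id, delay_days, ll_amount`; the generating seed is recorded
#' in a leading comment line.
#'
#' @param sets Trial sets from [build_trial_sets()].
#' @param path Output path.
#' @param seed Seed to record in the header comment.
#' @export
write_trial_sets <- function(sets, path, seed = NA) {
  df <- do.call(rbind, lapply(sets, function(s)
    cbind(set_id = s$set_id, s$trials)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# trial sets, seed=%s", seed), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
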