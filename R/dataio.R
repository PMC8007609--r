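#' Trial-level choice table I/O
#'
#' The on-disk format is a UTF-8 CSV with header and exactly these columns in
#' order: `subject_id, session, trial_index, set_id, ss_amount, ll_amount,
#' delay_days, choice, rt`. Sessions are labelled `lab`, `vr_neutral`,
#' `vr_gambling`. `choice` is 1 for the larger-later (LL) and 0 for the
#' smaller-sooner (SS) option; `rt` is the raw, unsigned response time in
#' seconds.
#'
#' @param path CSV file path.
#' @return `read_choice_table()`: a data frame of validated records with a
#'   `subject_id x session` grouping preserved in row order.
#' @export
read_choice_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_choice_records(df)
}

.CHOICE_COLS <- c("subject_id", "session", "trial_index", "set_id",
                  "ss_amount", "ll_amount", "delay_days", "choice", "rt")
.SESSIONS <- c("lab", "vr_neutral", "vr_gambling")

#' @rdname read_choice_table
#' @param records Data frame of choice records.
#' @export
write_choice_table <- function(records, path) {
  records <- validate_choice_records(records)
  utils::write.csv(records[, .CHOICE_COLS], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Validate trial-level choice records
#'
#' Checks the schema and every record-level invariant: LL/SS ratio in
#' [1.025, 3.85], delay in [1, 122] days, rt > 0, choice in \{0, 1\}.
#' Violations raise an error naming the first offending row.
#'
#' @param df Data frame with the choice-table columns.
#' @return The validated data frame (invisibly unchanged).
#' @export
validate_choice_records <- function(df) {
  missing_cols <- setdiff(.CHOICE_COLS, names(df))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  df <- df[, .CHOICE_COLS]
  for (col in c("trial_index", "set_id", "ss_amount", "ll_amount",
                "delay_days", "choice", "rt")) {
    v <- df[[col]]
    if (!is.numeric(v) || anyNA(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))) | is.na(v))[1]
      stop("non-numeric value in column '", col, "' at row ", bad)
    }
  }
  fail <- function(ok, what) {
    if (!all(ok)) stop(what, " at row ", which(!ok)[1])
  }
  fail(df$session %in% .SESSIONS, "unknown session label")
  fail(df$choice %in% c(0, 1), "choice outside {0,1}")
  fail(df$rt > 0, "rt <= 0")
  ratio <- df$ll_amount / df$ss_amount
  fail(ratio >= 1.025 - 1e-9 & ratio <= 3.85 + 1e-9,
       "ll_amount/ss_amount outside [1.025, 3.85]")
  fail(df$delay_days >= 1 & df$delay_days <= 122,
       "delay_days outside [1, 122]")
  fail(df$trial_index >= 0, "negative trial_index")
  df
}

#' RT preprocessing for model estimation
#'
#' Applies the two steps the diffusion-model likelihood requires, per
#' subject-session: (1) trim the `floor(trim_fraction * n)` fastest and the
#' same number of slowest trials on the raw (unsigned) RTs, ties at the trim
#' boundary broken by trial index (earlier trials kept); (2) sign-code the
#' retained RTs, multiplying RTs of smaller-sooner choices by -1 so the sign
#' carries the boundary. Trimming happens before sign-coding; applying it to
#' signed values would conflate choice with speed.
#'
#' @param records One subject's choice records for one session (unsigned rt).
#' @param trim_fraction Proportion trimmed per tail, in [0, 0.5). Default
#'   0.025 (the 2.5 percent fastest and slowest trials).
#' @return A `prepared_session` list with elements `records` (signed rt) and
#'   `n_trimmed`.
#' @export
preprocess_rts <- function(records, trim_fraction = 0.025) {
  stopifnot(trim_fraction >= 0, trim_fraction < 0.5)
  if (length(unique(records$subject_id)) > 1 ||
      length(unique(records$session)) > 1)
    stop("preprocess_rts expects a single subject-session")
  n <- nrow(records)
  if (n < 10) stop("fewer than 10 trials; trimming would not be meaningful")
  if (any(records$rt == 0)) stop("rt must be non-zero")
  raw <- abs(records$rt)   # trimming operates on raw unsigned RTs
  k <- floor(trim_fraction * n)
  keep <- rep(TRUE, n)
  if (k > 0) {
    # remove the k largest and k smallest raw RTs; among ties at the
    # boundary the later trial_index goes first, so earlier trials are kept
    ord_slow <- order(-raw, -records$trial_index)
    ord_fast <- order(raw, -records$trial_index)
    keep[ord_slow[seq_len(k)]] <- FALSE
    keep[ord_fast[seq_len(k)]] <- FALSE
  }
  out <- records[keep, , drop = FALSE]
  out$rt <- ifelse(out$choice == 1, abs(out$rt), -abs(out$rt))
  structure(list(records = out, n_trimmed = 2L * as.integer(k)),
            class = "prepared_session")
}

#' Electrodermal recording I/O
#'
#' CSV columns: `subject_id, session, time_s, scl_uS, scr_event, phase`,
#' with `phase` one of B (baseline), F (first exploration), S (second
#' exploration). Time must be strictly increasing within a subject-session
#' and each phase must span at least 300 s.
#'
#' @param path CSV file path.
#' @return Data frame of validated EDA samples.
#' @export
read_eda_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_eda_records(df)
}

#' @rdname read_eda_table
#' @param df Data frame of EDA samples.
#' @export
write_eda_table <- function(df, path) {
  df <- validate_eda_records(df)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_eda_table
#' @export
validate_eda_records <- function(df) {
  need <- c("subject_id", "session", "time_s", "scl_uS", "scr_event", "phase")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  if (!all(df$phase %in% c("B", "F", "S"))) stop("phase must be B, F or S")
  for (key in split(seq_len(nrow(df)),
                    interaction(df$subject_id, df$session, drop = TRUE))) {
    d <- df[key, ]
    if (any(diff(d$time_s) <= 0)) stop("time_s not strictly increasing")
    span <- tapply(d$time_s, d$phase, function(t) diff(range(t)))
    if (length(span) < 3) stop("all three phases (B, F, S) must be present")
    if (any(span < 300 - 1.5)) stop("each phase must span >= 300 s")
  }
  df
}
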