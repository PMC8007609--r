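# Small in-code fixtures shared across test files.

# one subject-session of n valid choice records with controllable RTs
make_records <- function(n = 96, subject = "S01", session = "lab",
                         rt = NULL, choice = NULL, seed = 1) {
  set.seed(seed)
  delays <- c(1, 15, 29, 94, 108, 122)
  mults <- seq(1.025, 3.85, length.out = 16)
  grid <- expand.grid(delay_days = delays, ll_amount = 20 * mults)
  idx <- rep_len(seq_len(nrow(grid)), n)
  data.frame(
    subject_id = subject, session = session,
    trial_index = seq_len(n) - 1L, set_id = 0L, ss_amount = 20,
    ll_amount = grid$ll_amount[idx], delay_days = grid$delay_days[idx],
    choice = if (is.null(choice)) rbinom(n, 1, 0.5) else rep_len(choice, n),
    rt = if (is.null(rt)) rlnorm(n, log(1.2), 0.3) else rep_len(rt, n))
}

# records generated by a deterministic hyperbolic agent (choice = LL iff
# discounted LL value exceeds the SS amount)
hyperbolic_agent_records <- function(log_k, n_rep = 1, seed = 1) {
  rec <- make_records(96 * n_rep, seed = seed)
  sv <- rec$ll_amount / (1 + exp(log_k) * rec$delay_days)
  rec$choice <- as.integer(sv > rec$ss_amount)
  rec
}

# tiny softmax cohort + per-session prepared lists, shared by slow tests
prepare_sessions <- function(choices) {
  out <- list()
  for (ses in unique(choices$session)) {
    d <- choices[choices$session == ses, ]
    out[[ses]] <- lapply(split(d, d$subject_id), preprocess_rts)
  }
  out
}

fast_mcmc <- function(seed = 1, chains = 2, warmup = 300, draws = 500)
  list(chains = chains, warmup = warmup, draws = draws, seed = seed)
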