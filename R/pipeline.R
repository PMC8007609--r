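#' Run configuration for the full study replica
#'
#' A single global seed fans out to per-stage substreams (stage-name hashed)
#' so stages are independently reproducible. Settings are echoed into the
#' report.
#'
#' @param out_dir Output directory for all artifacts.
#' @param cohort A [cohort_config()] (defines the synthetic study).
#' @param models Character vector of models to fit.
#' @param mcmc MCMC settings applied to every fit.
#' @param seed Global integer seed.
#' @param run_eda Whether to simulate and analyze EDA recordings.
#' @param verbose Print stage progress lines.
#' @return A `run_config` list.
#' @export
run_config <- function(out_dir = tempfile("ddm_run_"),
                       cohort = cohort_config(model = "ddms"),
                       models = c("ddm0", "ddml", "ddms"),
                       mcmc = list(chains = 4L, warmup = 1000L, draws = 4000L),
                       seed = 1L, run_eda = TRUE, verbose = TRUE) {
  structure(list(out_dir = out_dir, cohort = cohort, models = models,
                 mcmc = mcmc, seed = as.integer(seed), run_eda = run_eda,
                 verbose = verbose),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Recognized keys: `out_dir`, `models`, `seed`, `run_eda`, `mcmc:` (chains,
#' warmup, draws), `cohort:` (n_subjects, model, seed and any group
#' mean/trait/state overrides).
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  cohort_args <- y$cohort %||% list()
  cfg <- run_config(
    out_dir = y$out_dir %||% tempfile("ddm_run_"),
    cohort = do.call(cohort_config, cohort_args),
    models = y$models %||% c("ddm0", "ddml", "ddms"),
    mcmc = y$mcmc %||% list(chains = 4L, warmup = 1000L, draws = 4000L),
    seed = y$seed %||% 1L,
    run_eda = y$run_eda %||% TRUE)
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# deterministic per-stage seed derived from the global seed and stage name
.stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2^30)
}

#' Run the full pipeline: simulate, preprocess, fit, compare, summarize
#'
#' Stage order: synthetic cohort -> RT preprocessing -> hierarchical fits of
#' every requested model per session -> DIC comparison -> model-free AUC and
#' Friedman test -> reliability (ICC across sessions for AUC and all fitted
#' parameters of the best model) -> session contrasts -> EDA simulation and
#' phase contrasts -> JSON + Markdown report. Every artifact is written
#' under `config$out_dir`; numbers in the report are read from those
#' artifacts, not recomputed.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with all in-memory results and `paths` to the
#'   written artifacts.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(stage, ...) {
    if (config$verbose)
      message(sprintf("[%s] seed=%d %s", stage,
                      .stage_seed(config$seed, stage), sprintf(...)))
  }
  paths <- list()

  # --- simulate ---
  cohort <- config$cohort
  cohort$seed <- .stage_seed(config$seed, "simulate")
  sim <- simulate_cohort(cohort)
  paths$choices <- file.path(config$out_dir, "choices.csv")
  write_choice_table(sim$choices, paths$choices)
  paths$trial_sets <- file.path(config$out_dir, "trial_sets.csv")
  write_trial_sets(sim$trial_sets, paths$trial_sets, seed = cohort$seed)
  say("simulate", "%d rows", nrow(sim$choices))

  # --- preprocess ---
  choices <- read_choice_table(paths$choices)
  prepared <- list()
  for (ses in unique(choices$session)) {
    d <- choices[choices$session == ses, ]
    prepared[[ses]] <- lapply(split(d, d$subject_id), preprocess_rts)
  }
  say("preprocess", "%d sessions", length(prepared))

  # --- fit all models x sessions ---
  fits <- list()
  for (m in config$models) {
    fits[[m]] <- list()
    for (ses in names(prepared)) {
      mc <- config$mcmc
      mc$seed <- .stage_seed(config$seed, paste0("fit_", m, "_", ses))
      fits[[m]][[ses]] <- suppressWarnings(
        fit_hierarchical(m, prepared[[ses]], mcmc = mc))
      say("fit", "%s / %s", m, ses)
    }
  }
  for (m in names(fits)) for (ses in names(fits[[m]])) {
    f <- fits[[m]][[ses]]
    pm <- subject_posterior_means(f)
    df <- data.frame(subject_id = rownames(pm), pm, row.names = NULL)
    utils::write.csv(df, file.path(config$out_dir,
                                   sprintf("posterior_%s_%s.csv", m, ses)),
                     row.names = FALSE)
    write_fit_draws(f, file.path(config$out_dir,
                                 sprintf("posterior_%s_%s", m, ses)))
  }

  # --- compare ---
  dic_tab <- do.call(rbind, lapply(names(prepared), function(ses) {
    tab <- compare_models(lapply(config$models, function(m) fits[[m]][[ses]]))
    cbind(session = ses, tab)
  }))
  paths$dic <- file.path(config$out_dir, "dic.json")
  jsonlite::write_json(dic_tab, paths$dic, dataframe = "rows", digits = NA)
  say("compare", "best overall: %s",
      dic_tab$model[which.min(dic_tab$dic)])

  # --- model-free ---
  auc_tab <- auc_table(choices)
  paths$auc <- file.path(config$out_dir, "auc.csv")
  utils::write.csv(auc_tab, paths$auc, row.names = FALSE)
  auc_mat <- do.call(cbind, lapply(.SESSIONS, function(ses)
    auc_tab$auc[auc_tab$session == ses][order(
      auc_tab$subject_id[auc_tab$session == ses])]))
  colnames(auc_mat) <- .SESSIONS
  fried <- friedman_test(auc_mat)
  say("modelfree", "AUC Friedman chi2=%.3f p=%.3f", fried$chi2, fried$p)

  # --- reliability ---
  best_model <- dic_tab$model[which.min(dic_tab$dic)]
  best_fits <- fits[[best_model]][.SESSIONS]
  est_by_param <- function(param) {
    sapply(best_fits, function(f)
      subject_posterior_means(f)[order(rownames(subject_posterior_means(f))),
                                 param])
  }
  rel <- list(auc = unclass(icc_agreement(auc_mat)))
  for (p in model_params(best_model))
    rel[[p]] <- unclass(icc_agreement(est_by_param(p)))
  paths$reliability <- file.path(config$out_dir, "reliability.json")
  jsonlite::write_json(rel, paths$reliability, auto_unbox = TRUE, digits = NA)
  say("reliability", "AUC ICC=%.3f (%s)", rel$auc$icc, rel$auc$category)

  # --- contrasts ---
  ctr <- session_contrasts(best_fits,
                           seed = .stage_seed(config$seed, "contrasts"))
  paths$contrasts <- file.path(config$out_dir, "contrasts.csv")
  utils::write.csv(ctr, paths$contrasts, row.names = FALSE)
  say("contrasts", "%d rows", nrow(ctr))

  # --- EDA ---
  eda_res <- NULL
  if (config$run_eda) {
    eda <- rbind(
      simulate_eda(session = "vr_neutral",
                   seed = .stage_seed(config$seed, "eda_n")),
      simulate_eda(session = "vr_gambling",
                   seed = .stage_seed(config$seed, "eda_g")))
    paths$eda <- file.path(config$out_dir, "eda.csv")
    write_eda_table(eda, paths$eda)
    bins <- bin_eda_table(read_eda_table(paths$eda))
    eda_res <- phase_contrasts(bins)
    long <- do.call(rbind, lapply(names(bins), function(ses)
      do.call(rbind, lapply(names(bins[[ses]]), function(id) {
        pb <- bins[[ses]][[id]]
        data.frame(subject_id = id, session = ses, bin = pb$bin,
                   scl_pct = pb$scl_pct, nscr_pct = pb$nscr_pct)
      }))))
    utils::write.csv(long, file.path(config$out_dir, "eda_summary.csv"),
                     row.names = FALSE)
    paths$eda_contrasts <- file.path(config$out_dir, "eda_contrasts.json")
    jsonlite::write_json(eda_res, paths$eda_contrasts, dataframe = "rows",
                         digits = NA)
    say("eda", "%d contrasts", nrow(eda_res))
  }

  # --- report ---
  report <- list(
    seed = config$seed, models = config$models,
    cohort = unclass(config$cohort)[c("n_subjects", "sessions", "model")],
    mcmc = config$mcmc,
    r_version = as.character(getRversion()),
    dic = dic_tab, friedman_auc = fried, reliability = rel,
    wall_time_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  paths$report_json <- file.path(config$out_dir, "report.json")
  jsonlite::write_json(report, paths$report_json, auto_unbox = TRUE,
                       dataframe = "rows", digits = NA)
  md <- c(
    "# Temporal discounting reliability run", "",
    sprintf("- seed: %d", config$seed),
    sprintf("- cohort: %d subjects x 3 sessions, generating model %s",
            config$cohort$n_subjects, config$cohort$model),
    sprintf("- models fit: %s", paste(config$models, collapse = ", ")), "",
    "## DIC", "",
    paste(utils::capture.output(print(dic_tab, row.names = FALSE)),
          collapse = "\n"), "",
    sprintf("## AUC Friedman test: chi2 = %.3f, df = %d, p = %.3f",
            fried$chi2, fried$df, fried$p), "",
    "## Reliability (ICC, absolute agreement, mean of 3 sessions)", "",
    paste(vapply(names(rel), function(nmm)
      sprintf("- %s: ICC = %.3f [%.3f, %.3f], %s", nmm, rel[[nmm]]$icc,
              rel[[nmm]]$ci_low, rel[[nmm]]$ci_high, rel[[nmm]]$category),
      ""), collapse = "\n"))
  paths$report_md <- file.path(config$out_dir, "report.md")
  writeLines(md, paths$report_md)

  invisible(list(config = config, sim = sim, prepared = prepared,
                 fits = fits, dic = dic_tab, auc = auc_tab,
                 friedman = fried, reliability = rel, contrasts = ctr,
                 eda = eda_res, paths = paths))
}
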