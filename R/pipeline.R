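#' Default pipeline configuration
#'
#' All tunable defaults of the analysis chain in one structured list:
#' staircase geometry (267 ms start, 16.7 ms steps, 14 reversals),
#' screening rule (2.5 scaled MADs, consistency constant 1.4826, pooled
#' scope), generator conditions (see [study_config()]) and model options.
#' The list can be written to and read from YAML; [run_pipeline()] accepts
#' either the list or a YAML path.
#'
#' @param mode `"simulate"` (generate a synthetic study) or `"reproduce"`
#'   (load trial and questionnaire CSVs from `input` paths).
#' @param seed Integer master seed.
#' @param study Named list of [study_config()] overrides.
#' @param staircase Named list of [staircase_config()] overrides.
#' @param screening Named list: `k`, `b`, `scope`.
#' @param model Named list: `bayes` (logical; also run the MCMC models),
#'   `n_iter`, `n_burn`.
#' @param input Named list of paths: `trials`, `questionnaire` (reproduce
#'   mode), plus optional `column_map` (named character vector renaming
#'   deposit columns to the package schema).
#' @return Configuration list.
#' @export
pipeline_config <- function(mode = "simulate", seed = 1L, study = list(),
                            staircase = list(), screening = list(),
                            model = list(), input = list()) {
  list(mode = mode, seed = seed, study = study, staircase = staircase,
       screening = utils::modifyList(
         list(k = 2.5, b = 1.4826, scope = "pooled"), screening),
       model = utils::modifyList(
         list(bayes = FALSE, n_iter = 1000, n_burn = 500), model),
       input = input)
}

validate_columns <- function(df, spec, table, issues) {
  # spec: named list col -> validator returning logical vector (TRUE = ok)
  bad_rows <- rep(FALSE, nrow(df))
  for (col in names(spec)) {
    if (!col %in% names(df)) {
      issues(sprintf("%s: missing column '%s'", table, col))
      next
    }
    ok <- spec[[col]](df[[col]])
    if (any(!ok)) {
      issues(sprintf("%s: %d invalid values in '%s' (rows %s)", table,
                     sum(!ok), col,
                     paste(utils::head(which(!ok), 5), collapse = ", ")))
      bad_rows <- bad_rows | !ok
    }
  }
  bad_rows
}

#' Read and validate study tables
#'
#' Loads trial and questionnaire CSVs, optionally renaming deposit-specific
#' column names through a column map, and validates the schemas
#' exhaustively: every violation is listed (not just the first), offending
#' rows are rejected with reasons, and a missing-run summary is computed
#' against the complete participant x session x phase crossing.
#'
#' @param trials_path Path to the trial CSV.
#' @param questionnaire_path Path to the questionnaire CSV.
#' @param column_map Optional named character vector `new_name = old_name`
#'   applied to both tables.
#' @return List with `trials`, `questionnaire`, `issues` (character vector),
#'   `n_rejected`, and `missing_runs` (data frame of absent
#'   participant/session/phase combinations).
#' @export
read_study <- function(trials_path, questionnaire_path, column_map = NULL) {
  msgs <- character()
  issues <- function(m) msgs <<- c(msgs, m)
  rename <- function(df) {
    if (is.null(column_map)) return(df)
    for (new in names(column_map)) {
      old <- column_map[[new]]
      if (old %in% names(df)) names(df)[names(df) == old] <- new
    }
    df
  }
  trials <- rename(utils::read.csv(trials_path, stringsAsFactors = FALSE))
  quest <- rename(utils::read.csv(questionnaire_path, stringsAsFactors = FALSE))

  in_set <- function(vals) function(x) !is.na(x) & x %in% vals
  finite <- function(x) is.finite(suppressWarnings(as.numeric(x)))
  likert <- function(x) !is.na(x) & x %in% 1:5
  tspec <- list(participant = finite, session = finite,
                phase = in_set(c("pre", "post")),
                condition = in_set(c("endogenous", "exogenous")),
                cue_side = in_set(c("left", "right")),
                first_side = in_set(c("left", "right")),
                signed_soa_ms = finite,
                response = in_set(c("left", "right")),
                correct = function(x) !is.na(x) & x %in% c(TRUE, FALSE))
  qspec <- c(list(participant = finite, session = finite),
             stats::setNames(rep(list(likert), 27),
                             c(paste0("item_", 1:26), "control_q")))
  bad_t <- validate_columns(trials, tspec, "trials", issues)
  bad_q <- validate_columns(quest, qspec, "questionnaire", issues)
  n_rejected <- sum(bad_t) + sum(bad_q)
  trials <- trials[!bad_t, , drop = FALSE]
  quest <- quest[!bad_q, , drop = FALSE]

  runs <- unique(trials[c("participant", "session", "phase")])
  full <- expand.grid(participant = sort(unique(trials$participant)),
                      session = sort(unique(trials$session)),
                      phase = c("pre", "post"), stringsAsFactors = FALSE)
  present <- paste(runs$participant, runs$session, runs$phase)
  missing_runs <- full[!(paste(full$participant, full$session, full$phase)
                         %in% present), , drop = FALSE]
  rownames(missing_runs) <- NULL
  list(trials = trials, questionnaire = quest, issues = msgs,
       n_rejected = n_rejected, missing_runs = missing_runs)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Executes the complete chain -- simulate (or load) trial and questionnaire
#' data, fit psychometric functions and derive JND/PSS estimates, apply MAD
#' screening, score the AFSS, assemble the model table, and fit the
#' hierarchical moderation models (optionally also their Bayesian
#' counterparts) -- writing every intermediate table, an exclusion report,
#' coefficient tables and a run log to `outdir`. A stage failure aborts the
#' run naming the failing stage; tables written before the failure are
#' retained.
#'
#' Identical configuration and seed produce byte-identical estimate and
#' coefficient tables.
#'
#' @param config A [pipeline_config()] list or path to its YAML form.
#' @param outdir Output directory.
#' @return Invisibly, a list with the study, estimates, screen, flow table,
#'   model data, moderation fits and (if requested) Bayesian fits.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = tempfile("tojflow_")) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- utils::modifyList(pipeline_config(), config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  wcsv <- function(df, name) utils::write.csv(
    df, file.path(outdir, name), row.names = FALSE)

  if (config$mode == "simulate") {
    study <- run_stage("simulate", {
      cfg <- do.call(study_config, utils::modifyList(
        config$study, list(seed = config$seed)))
      scfg <- do.call(staircase_config, config$staircase)
      generate_study(cfg, measurement = "staircase", staircase = scfg)
    })
    trials <- study$trials
    quest <- study$questionnaire
    design <- study$design
    wcsv(trials, "trials.csv"); wcsv(quest, "questionnaire.csv")
  } else {
    loaded <- run_stage("read", read_study(config$input$trials_path,
                                           config$input$questionnaire_path,
                                           config$input$column_map))
    if (length(loaded$issues))
      writeLines(loaded$issues, file.path(outdir, "validation_issues.txt"))
    study <- NULL
    trials <- loaded$trials
    quest <- loaded$questionnaire
    design <- config$input$design %||%
      data.frame(participant = unique(trials$participant),
                 domain = NA_character_)
  }

  estimates <- run_stage("estimate", estimate_study(trials))
  wcsv(estimates, "estimates.csv")

  scr <- run_stage("screen", screen_estimates(
    estimates, k = config$screening$k, b = config$screening$b,
    scope = config$screening$scope))
  wcsv(scr$estimates, "estimates_screened.csv")
  writeLines(utils::capture.output(print(scr)),
             file.path(outdir, "exclusion_report.txt"))

  flow <- run_stage("score", score_flow_table(quest))
  wcsv(flow, "flow_scores.csv")

  mdata <- run_stage("model_data", build_model_data(scr, flow, design))
  wcsv(mdata, "model_input.csv")

  fits <- run_stage("model", fit_moderation_models(mdata))
  wcsv(fits$jnd$coefficients, "coef_jnd.csv")
  wcsv(fits$pss$coefficients, "coef_pss.csv")

  bayes <- NULL
  if (isTRUE(config$model$bayes)) {
    bayes <- run_stage("bayes", list(
      jnd = bayesian_moderation(mdata, "JND", n_iter = config$model$n_iter,
                                n_burn = config$model$n_burn,
                                seed = config$seed),
      pss = bayesian_moderation(mdata, "PSS_distance",
                                n_iter = config$model$n_iter,
                                n_burn = config$model$n_burn,
                                seed = config$seed)))
    wcsv(bayes$jnd$summary, "bayes_jnd.csv")
    wcsv(bayes$pss$summary, "bayes_pss.csv")
  }

  report <- c(utils::capture.output(print(fits)),
              "", utils::capture.output(print(scr)))
  writeLines(report, file.path(outdir, "report.txt"))

  cfg_path <- file.path(outdir, "config.yaml")
  yaml::write_yaml(config, cfg_path)
  log <- c(sprintf("tojflow %s", as.character(utils::packageVersion("tojflow"))),
           sprintf("run at: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
           sprintf("seed: %d", config$seed),
           sprintf("config md5: %s", unname(tools::md5sum(cfg_path))),
           sprintf("trials: %d rows", if (is.null(trials)) 0L else nrow(trials)),
           sprintf("estimates: %d rows (%d after screening)",
                   nrow(estimates), nrow(scr$estimates)))
  writeLines(log, file.path(outdir, "run_log.txt"))

  invisible(list(study = study, trials = trials, estimates = estimates,
                 screen = scr, flow = flow, model_data = mdata,
                 fits = fits, bayes = bayes, outdir = outdir,
                 config = config))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
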