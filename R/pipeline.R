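#' End-to-end pipeline stages
#'
#' Three functions mirror the stages a study runs through, each reading
#' and writing the package's delimited formats so a whole analysis can be
#' scripted (the `inst/scripts/rehabelo` wrapper exposes them as shell
#' subcommands):
#'
#' * `run_simulate()` generates synthetic data — either the 20-patient
#'   feasibility fixture or a full cohort — and writes the execution log
#'   (plus cohort table and generator provenance).
#' * `run_rate()` turns an execution log into ratings: optional
#'   task-frequency filter, first-n truncation, match building, rating
#'   run; writes the leaderboard (and optionally the match log).
#' * `run_stratify_model()` joins a cohort table with a leaderboard,
#'   stratifies patients into rating terciles, writes the stratified
#'   summary, and fits the four stepwise outcome models with the
#'   rating-ablation comparison.
#'
#' @param out_dir Output directory (created if missing).
#' @param preset `"cohort"` or `"feasibility"` for `run_simulate()`.
#' @param spec A [cohort_spec()] or [feasibility_spec()]; defaults follow
#'   the preset.
#' @param seed Integer seed recorded in the provenance file.
#' @param execution_log,cohort_file,leaderboard_file Input paths.
#' @param config A [rating_config()]; `run_rate()` defaults to Stephenson
#'   (the cohort engine) unless `preset = "feasibility"`, which uses
#'   Glicko.
#' @param rule An [outcome_rule()].
#' @param truncate_n Keep each patient's first n executions (NULL for
#'   all; default 50).
#' @param filter_mode,filter_threshold Optional [filter_frequent_tasks()]
#'   arguments; NULL skips the filter.
#' @param period_scheme,opponent_scheme Passed to [build_match_log()].
#' @param candidates Candidate predictors for the outcome models.
#' @return Each stage returns (invisibly) a list of the objects it wrote.
#' @name pipeline
NULL

#' @rdname pipeline
#' @export
run_simulate <- function(out_dir, preset = c("cohort", "feasibility"),
                         spec = NULL, seed = 1L) {
  preset <- match.arg(preset)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (preset == "feasibility") {
    if (is.null(spec)) spec <- feasibility_spec()
    executions <- generate_feasibility_case(spec, seed = seed)
    cohort <- NULL
  } else {
    if (is.null(spec)) spec <- cohort_spec()
    sim <- generate_cohort(spec, seed = seed)
    executions <- sim$executions
    cohort <- sim$cohort
    write_cohort(cohort, file.path(out_dir, "cohort.csv"))
  }
  write_execution_log(executions, file.path(out_dir, "executions.csv"))
  prov <- c(list(preset = preset, seed = as.integer(seed)),
            lapply(unclass(spec), function(x)
              if (is.numeric(x) || is.character(x)) x else NULL))
  yaml::write_yaml(prov[!vapply(prov, is.null, logical(1))],
                   file.path(out_dir, "simulation-spec.yml"))
  invisible(list(executions = executions, cohort = cohort, spec = spec))
}

#' @rdname pipeline
#' @export
run_rate <- function(execution_log, out_dir,
                     preset = c("cohort", "feasibility"),
                     config = NULL, rule = NULL, truncate_n = 50,
                     filter_mode = NULL, filter_threshold = 0.85,
                     period_scheme = NULL, opponent_scheme = NULL) {
  preset <- match.arg(preset)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  executions <- if (is.data.frame(execution_log)) execution_log
                else read_execution_log(execution_log)
  if (nrow(executions) == 0L) stop_input("empty execution log")
  if (is.null(config))
    config <- if (preset == "feasibility") rating_config("glicko")
              else rating_config("stephenson")
  if (is.null(rule))
    rule <- outcome_rule(if (preset == "feasibility") "feasibility" else "cohort")
  if (is.null(period_scheme))
    period_scheme <- if (preset == "feasibility") "per_execution_round"
                     else "per_session"
  if (is.null(opponent_scheme))
    opponent_scheme <- if (preset == "feasibility") "task"
                       else "task_by_difficulty"
  report <- NULL
  if (!is.null(filter_mode)) {
    filtered <- filter_frequent_tasks(executions, filter_mode, filter_threshold)
    executions <- filtered$executions
    report <- filtered$report
    writeLines(utils::capture.output(print(report)),
               file.path(out_dir, "task-filter.txt"))
  }
  if (!is.null(truncate_n)) executions <- truncate_first_n(executions, truncate_n)
  matches <- build_match_log(executions, rule, period_scheme, opponent_scheme)
  fit <- rate_players(matches, config)
  write_match_log(matches, file.path(out_dir, "matches.csv"))
  write_leaderboard(fit, file.path(out_dir, "leaderboard.csv"))
  invisible(list(fit = fit, matches = matches, filter_report = report))
}

#' @rdname pipeline
#' @export
run_stratify_model <- function(cohort_file, leaderboard_file, out_dir,
                               execution_log = NULL,
                               candidates = c("early_rating", "age_years",
                                              "sex", "length_of_stay_days")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- if (is.data.frame(cohort_file)) cohort_file
            else read_cohort(cohort_file)
  lb <- if (is.data.frame(leaderboard_file)) leaderboard_file
        else read_leaderboard(leaderboard_file)
  ratings <- stats::setNames(lb$rating, lb$player)
  orphans <- setdiff(cohort$patient_id, names(ratings))
  if (length(orphans))
    stop_input("no rating for patient(s): %s",
               paste(utils::head(orphans, 10), collapse = ", "))
  cohort$early_rating <- as.numeric(ratings[cohort$patient_id])
  cohort$elo_group <- stratify_terciles(
    stats::setNames(cohort$early_rating, cohort$patient_id))[cohort$patient_id]
  executions <- if (is.null(execution_log)) NULL
                else if (is.data.frame(execution_log)) execution_log
                else read_execution_log(execution_log)
  summary_tab <- group_summary(cohort, executions)
  utils::write.csv(summary_tab$stats, file.path(out_dir, "group-summary.csv"),
                   row.names = FALSE)
  write_cohort(cohort, file.path(out_dir, "cohort-stratified.csv"))

  models <- list()
  model_defs <- list(
    ravlt075_discharge  = list(outcome = "ravlt075_dis", family = "linear",
                               extra = "ravlt075_adm"),
    digits_discharge    = list(outcome = "digits_dis", family = "linear",
                               extra = "digits_adm"),
    ravlt075_improvement = list(outcome = ".imp075", family = "logistic",
                                extra = "ravlt075_adm"),
    digits_improvement  = list(outcome = ".impdig", family = "logistic",
                               extra = "digits_adm"))
  cohort$.imp075 <- as.numeric(improvement_flags(cohort$ravlt075_adm,
                                                 cohort$ravlt075_dis, 5))
  cohort$.impdig <- as.numeric(improvement_flags(cohort$digits_adm,
                                                 cohort$digits_dis, 1))
  rows <- list()
  for (nm in names(model_defs)) {
    def <- model_defs[[nm]]
    cand <- unique(c(candidates, def$extra))
    cand <- cand[cand %in% names(cohort)]
    fit_with <- forward_stepwise(cohort, def$outcome, cand, def$family)
    fit_without <- forward_stepwise(cohort, def$outcome,
                                    setdiff(cand, "early_rating"), def$family)
    abl <- ablation_compare(fit_with, fit_without)
    models[[nm]] <- list(with = fit_with, without = fit_without,
                         ablation = abl)
    rows[[nm]] <- data.frame(model = nm, criterion = abl$criterion,
                             with_rating = abl$value_with,
                             without_rating = abl$value_without,
                             delta = abl$delta)
    cf <- fit_with$coefficients
    cf$model <- nm
    utils::write.csv(cf, file.path(out_dir, paste0("model-", nm, ".csv")),
                     row.names = FALSE)
  }
  utils::write.csv(do.call(rbind, rows), file.path(out_dir, "ablation.csv"),
                   row.names = FALSE)
  invisible(list(cohort = cohort, summary = summary_tab, models = models))
}
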