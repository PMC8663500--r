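#' Win/draw/loss rule for task-compliance results
#'
#' Maps the 0-100 compliance result of one task execution to a match score
#' for the patient. Two named presets exist:
#' \describe{
#'   \item{`"cohort"`}{result <= 39 is a loss (the task wins), 40-64 is a
#'     draw, >= 65 is a win for the patient. Non-integer results falling
#'     strictly inside the gaps (39, 40) or (64, 65) are resolved by
#'     `boundary_policy` (default: draw).}
#'   \item{`"feasibility"`}{no draws: > 50 is a win, < 50 a loss; exactly
#'     50 is resolved by `boundary_policy` (default: loss).}
#' }
#'
#' @param rule_name `"cohort"` or `"feasibility"`.
#' @param boundary_policy `"draw"`, `"loss"` or `"win"` for results not
#'   covered by the bands.
#' @return An object of class `"outcome_rule"`.
#' @examples
#' score_execution(c(39, 40, 64, 65), outcome_rule("cohort"))
#' score_execution(c(49, 50, 51), outcome_rule("feasibility"))
#' @export
outcome_rule <- function(rule_name = c("cohort", "feasibility"),
                         boundary_policy = NULL) {
  rule_name <- match.arg(rule_name)
  if (is.null(boundary_policy))
    boundary_policy <- if (rule_name == "cohort") "draw" else "loss"
  boundary_policy <- match.arg(boundary_policy, c("draw", "loss", "win"))
  structure(list(rule_name = rule_name,
                 loss_max = if (rule_name == "cohort") 39 else 50,
                 draw_low = if (rule_name == "cohort") 40 else NA_real_,
                 draw_high = if (rule_name == "cohort") 64 else NA_real_,
                 win_min = if (rule_name == "cohort") 65 else 50,
                 boundary_policy = boundary_policy),
            class = "outcome_rule")
}

#' @export
print.outcome_rule <- function(x, ...) {
  if (x$rule_name == "cohort") {
    cat(sprintf("Outcome rule 'cohort': loss <= %g, draw %g-%g, win >= %g (gaps -> %s)\n",
                x$loss_max, x$draw_low, x$draw_high, x$win_min,
                x$boundary_policy))
  } else {
    cat(sprintf("Outcome rule 'feasibility': win > 50, loss < 50 (50 -> %s)\n",
                x$boundary_policy))
  }
  invisible(x)
}

#' Score task executions as match results
#'
#' @param result Numeric vector of compliance results in [0, 100].
#' @param rule An [outcome_rule()].
#' @return Numeric vector of scores in {0, 0.5, 1} from the patient's
#'   side (the task opponent implicitly scores the complement).
#' @export
score_execution <- function(result, rule = outcome_rule("cohort")) {
  if (!is.numeric(result) || any(!is.finite(result)))
    stop_input("'result' must be finite numeric")
  if (any(result < 0 | result > 100))
    stop_input("results must lie in [0, 100]")
  boundary <- switch(rule$boundary_policy, draw = 0.5, loss = 0, win = 1)
  if (rule$rule_name == "cohort") {
    out <- rep(boundary, length(result))
    out[result <= rule$loss_max] <- 0
    out[result >= rule$draw_low & result <= rule$draw_high] <- 0.5
    out[result >= rule$win_min] <- 1
  } else {
    out <- rep(boundary, length(result))
    out[result < 50] <- 0
    out[result > 50] <- 1
  }
  out
}

#' Build a rated match log from raw task executions
#'
#' Converts each execution into one match: the patient as player_a, the
#' task as opponent, scored by the outcome rule. The rating-period index
#' comes from the chosen scheme: `"per_session"` uses the session index,
#' `"per_execution_round"` uses the within-patient execution order (the
#' k-th execution of every patient lands in period k), `"single"` puts
#' everything in one period. Opponents are either the task id or the task
#' id qualified by difficulty level (`"task_by_difficulty"`, the default,
#' since the same task at a harder configuration is a stronger opponent).
#'
#' @param executions Data frame of executions with columns `patient_id`,
#'   `task_id`, `difficulty_level`, `session_index`, `execution_index`,
#'   `result`.
#' @param rule An [outcome_rule()].
#' @param period_scheme `"per_session"`, `"per_execution_round"` or
#'   `"single"`.
#' @param opponent_scheme `"task_by_difficulty"` or `"task"`.
#' @return Data frame with columns `period`, `player_a`, `player_b`,
#'   `score_a`; exactly one row per execution.
#' @export
build_match_log <- function(executions,
                            rule = outcome_rule("cohort"),
                            period_scheme = c("per_session",
                                              "per_execution_round",
                                              "single"),
                            opponent_scheme = c("task_by_difficulty",
                                                "task")) {
  period_scheme <- match.arg(period_scheme)
  opponent_scheme <- match.arg(opponent_scheme)
  validate_executions(executions)
  if (nrow(executions) == 0L)
    return(data.frame(period = integer(0), player_a = character(0),
                      player_b = character(0), score_a = numeric(0)))
  period <- switch(period_scheme,
    per_session = as.integer(executions$session_index),
    per_execution_round = stats::ave(executions$execution_index,
                                     executions$patient_id,
                                     FUN = function(x) rank(x, ties.method = "first")),
    single = rep(1L, nrow(executions)))
  opponent <- if (opponent_scheme == "task") {
    as.character(executions$task_id)
  } else {
    paste0(executions$task_id, "@L", executions$difficulty_level)
  }
  data.frame(period = as.integer(period),
             player_a = as.character(executions$patient_id),
             player_b = opponent,
             score_a = score_execution(executions$result, rule),
             stringsAsFactors = FALSE)
}

validate_executions <- function(executions) {
  need <- c("patient_id", "task_id", "difficulty_level", "session_index",
            "execution_index", "result")
  if (!is.data.frame(executions) || !all(need %in% names(executions)))
    stop_input("executions must be a data frame with columns: %s",
               paste(need, collapse = ", "))
  if (nrow(executions) == 0L) return(invisible(executions))
  if (any(!executions$difficulty_level %in% 1:3))
    stop_input("difficulty_level must be 1, 2 or 3")
  if (any(executions$result < 0 | executions$result > 100))
    stop_input("results must lie in [0, 100]")
  key <- paste(executions$patient_id, executions$execution_index)
  if (anyDuplicated(key))
    stop_input("(patient_id, execution_index) pairs must be unique")
  invisible(executions)
}

#' Keep each patient's first n task executions
#'
#' Early ratings are computed from the first executions only (50 in the
#' cohort analysis), so that the stratification is available within the
#' first weeks of rehabilitation.
#'
#' @param executions Execution data frame (see [build_match_log()]).
#' @param n Number of executions to keep per patient.
#' @return The truncated data frame, in the original row order, with an
#'   attribute `"short_patients"`: ids of patients that had fewer than `n`
#'   executions (kept in full).
#' @export
truncate_first_n <- function(executions, n = 50) {
  validate_executions(executions)
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop_input("'n' must be a positive integer")
  keep <- stats::ave(executions$execution_index, executions$patient_id,
                     FUN = function(x) rank(x, ties.method = "first")) <= n
  counts <- table(executions$patient_id)
  out <- executions[keep, , drop = FALSE]
  attr(out, "short_patients") <- names(counts)[counts < n]
  out
}

#' Drop infrequently executed tasks
#'
#' Two modes: `"coverage"` ranks tasks by execution count (ties broken by
#' task id) and retains the smallest prefix whose cumulative executions
#' reach `threshold` as a fraction of the total; `"min_count"` retains
#' every task with at least `threshold` executions.
#'
#' @param executions Execution data frame.
#' @param mode `"coverage"` or `"min_count"`.
#' @param threshold Coverage fraction in (0, 1] or minimum count.
#' @return List with `executions` (the retained rows) and `report`, a
#'   `task_filter_report` containing counts and percentages (rounded to
#'   two decimals).
#' @examples
#' # three tasks with counts 5, 3, 2; 80% coverage keeps the top two
#' ex <- data.frame(patient_id = "p", task_id = rep(c("A", "B", "C"), c(5, 3, 2)),
#'                  difficulty_level = 1, session_index = 1,
#'                  execution_index = 1:10, result = 70)
#' filter_frequent_tasks(ex, "coverage", 0.8)$report$retained_task_ids
#' @export
filter_frequent_tasks <- function(executions, mode = c("coverage", "min_count"),
                                  threshold = 0.85) {
  mode <- match.arg(mode)
  validate_executions(executions)
  if (nrow(executions) == 0L) stop_input("no executions to filter")
  if (threshold <= 0) stop_input("'threshold' must be > 0")
  counts <- table(as.character(executions$task_id))
  ord <- order(-as.integer(counts), names(counts))
  counts <- counts[ord]
  if (mode == "coverage") {
    cum <- cumsum(as.integer(counts))
    need <- threshold * sum(counts)
    k <- which(cum >= need)[1]
    if (is.na(k)) k <- length(counts)
    retained <- names(counts)[seq_len(k)]
  } else {
    retained <- names(counts)[as.integer(counts) >= threshold]
  }
  keep <- as.character(executions$task_id) %in% retained
  report <- task_filter_report(total_tasks = length(counts),
                               retained_tasks = length(retained),
                               total_executions = nrow(executions),
                               retained_executions = sum(keep),
                               retained_task_ids = retained)
  list(executions = executions[keep, , drop = FALSE], report = report)
}

#' Task-filter report
#'
#' Bookkeeping of a task-frequency filter: how many tasks and executions
#' survived, and the corresponding percentages (two decimals).
#'
#' @param total_tasks,retained_tasks,total_executions,retained_executions
#'   Counts.
#' @param retained_task_ids Character vector of retained task ids.
#' @return Object of class `"task_filter_report"`.
#' @export
task_filter_report <- function(total_tasks, retained_tasks,
                               total_executions, retained_executions,
                               retained_task_ids = character(0)) {
  if (retained_tasks > total_tasks || retained_executions > total_executions)
    stop_input("retained counts cannot exceed totals")
  structure(list(
    total_tasks = as.integer(total_tasks),
    retained_tasks = as.integer(retained_tasks),
    total_executions = as.integer(total_executions),
    retained_executions = as.integer(retained_executions),
    task_fraction_pct = round(100 * retained_tasks / total_tasks, 2),
    execution_coverage_pct = round(100 * retained_executions / total_executions, 2),
    retained_task_ids = retained_task_ids
  ), class = "task_filter_report")
}

#' @export
print.task_filter_report <- function(x, ...) {
  cat(sprintf("Task filter: %d/%d tasks retained (%.2f%%), %d/%d executions (%.2f%%)\n",
              x$retained_tasks, x$total_tasks, x$task_fraction_pct,
              x$retained_executions, x$total_executions,
              x$execution_coverage_pct))
  invisible(x)
}
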