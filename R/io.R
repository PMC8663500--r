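#' Read and write the pipeline's delimited files
#'
#' All files are plain comma-separated UTF-8 text with a mandatory
#' header. Four layouts are used: the execution log
#' (`patient_id,task_id,difficulty_level,session_index,execution_index,result`),
#' the match log (`period,player_a,player_b,score_a`), the leaderboard
#' (`player,rating,deviation,volatility,games,wins,draws,losses`, sorted
#' rating-descending) and the cohort table. Malformed rows abort the read
#' with their line numbers.
#'
#' @param path File path.
#' @param executions,matches,fit,cohort Objects to write.
#' @return The read functions return validated data frames;
#'   `read_leaderboard()` returns the leaderboard data frame.
#' @name pipeline-io
NULL

read_csv_checked <- function(path, required, validator = NULL) {
  if (!file.exists(path)) stop_input("file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop_input("%s: missing column(s) %s", path,
               paste(missing_cols, collapse = ", "))
  if (!is.null(validator)) {
    bad <- validator(df)
    if (length(bad))
      stop_input("%s: malformed row(s) at line(s) %s", path,
                 paste(utils::head(bad + 1L, 20L), collapse = ", "))
  }
  df
}

#' @rdname pipeline-io
#' @export
read_execution_log <- function(path) {
  df <- read_csv_checked(
    path,
    c("patient_id", "task_id", "difficulty_level", "session_index",
      "execution_index", "result"),
    validator = function(df)
      which(!is.finite(df$result) | df$result < 0 | df$result > 100 |
              !df$difficulty_level %in% 1:3))
  validate_executions(df)
  df
}

#' @rdname pipeline-io
#' @export
write_execution_log <- function(executions, path) {
  validate_executions(executions)
  utils::write.csv(executions, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname pipeline-io
#' @export
read_match_log <- function(path) {
  read_csv_checked(path, c("period", "player_a", "player_b", "score_a"),
                   validator = function(df)
                     which(!df$score_a %in% c(0, 0.5, 1) | df$period < 0))
}

#' @rdname pipeline-io
#' @export
write_match_log <- function(matches, path) {
  utils::write.csv(matches, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname pipeline-io
#' @export
write_leaderboard <- function(fit, path) {
  lb <- if (inherits(fit, "rating_fit")) leaderboard(fit) else fit
  utils::write.csv(lb, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname pipeline-io
#' @export
read_leaderboard <- function(path) {
  read_csv_checked(path, c("player", "rating", "deviation", "volatility",
                           "games", "wins", "draws", "losses"))
}

#' @rdname pipeline-io
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname pipeline-io
#' @export
read_cohort <- function(path) {
  read_csv_checked(path, c("patient_id", "ravlt075_adm", "ravlt075_dis",
                           "digits_adm", "digits_dis"))
}

#' Read or write a rating configuration file
#'
#' A flat key-value (YAML) file mirroring the [rating_config()] fields.
#' Unknown keys are rejected.
#'
#' @param path File path.
#' @param config A [rating_config()].
#' @export
read_rating_config <- function(path) {
  vals <- yaml::read_yaml(path)
  allowed <- names(formals(rating_config))
  unknown <- setdiff(names(vals), allowed)
  if (length(unknown))
    stop_input("unknown rating-config key(s): %s", paste(unknown, collapse = ", "))
  do.call(rating_config, vals)
}

#' @rdname read_rating_config
#' @export
write_rating_config <- function(config, path) {
  stopifnot(inherits(config, "rating_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
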