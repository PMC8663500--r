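#' Fit a rating model to a match log
#'
#' The central fitting function of the package: processes a log of rated
#' matches in batches (rating periods) through one of the four engines and
#' returns the full rating history plus the final leaderboard. Within a
#' period every update uses pre-period opponent states, so permuting
#' matches inside a period never changes the result. Players are created
#' on first appearance with the configured initial rating, deviation and
#' volatility unless supplied through `initial_states`.
#'
#' @param matches Data frame with columns `period` (non-negative integer,
#'   processed in ascending order), `player_a`, `player_b` and `score_a`
#'   in {0, 0.5, 1} (the score from player_a's side; player_b implicitly
#'   scores `1 - score_a`). Typically produced by [build_match_log()].
#' @param config A [rating_config()] choosing the engine and its tunables.
#' @param initial_states Optional [player_states()] data frame of
#'   pre-rated players.
#' @return An object of class `"rating_fit"` with components
#'   \describe{
#'     \item{config}{the configuration used;}
#'     \item{snapshots}{named list, one `player_states` data frame per
#'       processed period (post-period);}
#'     \item{final}{the leaderboard: final states sorted by rating
#'       descending, ties broken by player id;}
#'     \item{n_matches, periods}{bookkeeping.}
#'   }
#' @examples
#' m <- data.frame(period = 1, player_a = "A", player_b = "B", score_a = 1)
#' fit <- rate_players(m, rating_config("elo", k_factor = 32))
#' leaderboard(fit)
#' @export
rate_players <- function(matches, config = rating_config(),
                         initial_states = NULL) {
  if (!is.data.frame(matches))
    stop_input("'matches' must be a data frame")
  if (nrow(matches) && !"period" %in% names(matches))
    stop_input("'matches' needs a 'period' column")
  states <- if (is.null(initial_states)) {
    player_states(character(0), config)
  } else {
    validate_states(initial_states)
  }
  engine <- switch(config$system,
                   elo        = elo_update_period,
                   glicko     = glicko_update_period,
                   glicko2    = glicko2_update_period,
                   stephenson = stephenson_update_period)
  snapshots <- list()
  periods <- integer(0)
  if (nrow(matches)) {
    if (any(matches$period < 0)) stop_input("period indices must be >= 0")
    periods <- sort(unique(as.integer(matches$period)))
    for (p in periods) {
      block <- matches[matches$period == p, , drop = FALSE]
      new_players <- setdiff(unique(c(as.character(block$player_a),
                                      as.character(block$player_b))),
                             states$player)
      if (length(new_players)) {
        states <- rbind(states, player_states(new_players, config))
        class(states) <- c("player_states", "data.frame")
      }
      states <- engine(states, block, config)
      snapshots[[as.character(p)]] <- states
    }
  }
  final <- states[order(-states$rating, states$player), , drop = FALSE]
  rownames(final) <- NULL
  structure(list(config = config,
                 snapshots = snapshots,
                 final = final,
                 n_matches = nrow(matches),
                 periods = periods),
            class = "rating_fit")
}

#' Final leaderboard of a rating fit
#'
#' @param fit A [rate_players()] result.
#' @return A data frame sorted by rating descending (ties by player id).
#' @export
leaderboard <- function(fit) {
  stopifnot(inherits(fit, "rating_fit"))
  fit$final
}

#' Per-period rating history in long format
#'
#' @param fit A [rate_players()] result.
#' @return Data frame with columns `period`, `player`, `rating`,
#'   `deviation`, `volatility`, `games`.
#' @export
rating_history <- function(fit) {
  stopifnot(inherits(fit, "rating_fit"))
  if (!length(fit$snapshots))
    return(data.frame(period = integer(0), player = character(0),
                      rating = numeric(0), deviation = numeric(0),
                      volatility = numeric(0), games = integer(0)))
  do.call(rbind, lapply(names(fit$snapshots), function(p) {
    s <- fit$snapshots[[p]]
    data.frame(period = as.integer(p), player = s$player, rating = s$rating,
               deviation = s$deviation, volatility = s$volatility,
               games = s$games, stringsAsFactors = FALSE)
  }))
}

#' @export
print.rating_fit <- function(x, ...) {
  cat(sprintf("Rating fit (%s): %d players, %d matches over %d period(s)\n",
              x$config$system, nrow(x$final), x$n_matches,
              length(x$periods)))
  if (nrow(x$final)) {
    top <- utils::head(x$final, 5L)
    cat("Leaderboard (top", nrow(top), "):\n")
    print(data.frame(player = top$player,
                     rating = round(top$rating),
                     deviation = round(top$deviation, 2),
                     record = sprintf("%d-%d-%d", top$wins, top$draws,
                                      top$losses)),
          row.names = FALSE)
  }
  invisible(x)
}

#' @export
summary.rating_fit <- function(object, ...) {
  out <- list(system = object$config$system,
              n_players = nrow(object$final),
              n_matches = object$n_matches,
              n_periods = length(object$periods),
              rating_range = range(object$final$rating),
              leaderboard = object$final)
  class(out) <- "summary.rating_fit"
  out
}

#' @export
print.summary.rating_fit <- function(x, ...) {
  cat(sprintf("%s rating over %d periods: %d players, %d matches\n",
              x$system, x$n_periods, x$n_players, x$n_matches))
  cat(sprintf("Rating range: %.0f .. %.0f\n",
              x$rating_range[1], x$rating_range[2]))
  print(x$leaderboard, row.names = FALSE)
  invisible(x)
}

#' @export
coef.rating_fit <- function(object, ...) {
  stats::setNames(object$final$rating, object$final$player)
}

#' Predict expected scores for new pairings
#'
#' Uses the final ratings to compute the logistic expected score for each
#' requested pairing. Players absent from the fit are assigned the
#' configured initial rating.
#'
#' @param object A [rate_players()] result.
#' @param newdata Data frame with columns `player_a` and `player_b`.
#' @param ... Unused.
#' @return Numeric vector of expected scores for player_a.
#' @export
predict.rating_fit <- function(object, newdata, ...) {
  if (missing(newdata) || !all(c("player_a", "player_b") %in% names(newdata)))
    stop_input("'newdata' must have columns player_a and player_b")
  r <- coef(object)
  get_r <- function(p) ifelse(p %in% names(r), r[p],
                              object$config$initial_rating)
  expected_score(get_r(as.character(newdata$player_a)),
                 get_r(as.character(newdata$player_b)),
                 object$config)
}

#' Plot rating trajectories
#'
#' One line per player across rating periods.
#'
#' @param x A [rate_players()] result.
#' @param players Optional character vector restricting the plot.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.rating_fit <- function(x, players = NULL, ...) {
  h <- rating_history(x)
  if (!nrow(h)) stop_input("nothing to plot: no periods were processed")
  if (!is.null(players)) h <- h[h$player %in% players, , drop = FALSE]
  wide <- stats::reshape(h[, c("period", "player", "rating")],
                         idvar = "period", timevar = "player",
                         direction = "wide")
  wide <- wide[order(wide$period), , drop = FALSE]
  mat <- as.matrix(wide[, -1, drop = FALSE])
  graphics::matplot(wide$period, mat, type = "l", lty = 1,
                    xlab = "Rating period", ylab = "Rating", ...)
  invisible(x)
}
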