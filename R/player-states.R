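#' Create a table of player states
#'
#' A player state holds everything a rating engine tracks about one rated
#' entity (a patient or a task opponent): the rating, its deviation
#' (Glicko RD, the uncertainty of the rating), the Glicko-2 volatility, and
#' win/draw/loss tallies. States are stored as a plain data frame with one
#' row per player so the engines can work vectorised.
#'
#' @param players Character vector of unique player identifiers.
#' @param config A [rating_config()] supplying initial rating, deviation
#'   and volatility.
#' @param rating,deviation,volatility Optional numeric vectors overriding
#'   the configured initial values (recycled to `length(players)`).
#' @return A data frame of class `"player_states"` with columns `player`,
#'   `rating`, `deviation`, `volatility`, `games`, `wins`, `draws`,
#'   `losses`.
#' @examples
#' player_states(c("id1", "Maze"), rating_config())
#' @export
player_states <- function(players, config = rating_config(),
                          rating = NULL, deviation = NULL, volatility = NULL) {
  players <- as.character(players)
  if (anyDuplicated(players)) stop_input("duplicated player ids")
  n <- length(players)
  st <- data.frame(
    player     = players,
    rating     = rep_len(if (is.null(rating)) config$initial_rating else rating, n),
    deviation  = rep_len(if (is.null(deviation)) config$initial_deviation else deviation, n),
    volatility = rep_len(if (is.null(volatility)) config$initial_volatility else volatility, n),
    games = integer(n), wins = integer(n), draws = integer(n),
    losses = integer(n),
    stringsAsFactors = FALSE
  )
  validate_states(st)
  class(st) <- c("player_states", "data.frame")
  st
}

validate_states <- function(states) {
  need <- c("player", "rating", "deviation", "volatility",
            "games", "wins", "draws", "losses")
  if (!all(need %in% names(states)))
    stop_input("player states must have columns: %s", paste(need, collapse = ", "))
  if (any(!is.finite(states$rating))) stop_input("non-finite rating in states")
  if (any(states$deviation <= 0)) stop_input("deviations must be > 0")
  if (any(states$volatility <= 0)) stop_input("volatilities must be > 0")
  if (any(states$games != states$wins + states$draws + states$losses))
    stop_input("games must equal wins + draws + losses")
  invisible(states)
}

# Validate a block of matches against the current states.
# Matches: data.frame with player_a, player_b, score_a (and usually period).
check_matches <- function(states, matches) {
  need <- c("player_a", "player_b", "score_a")
  if (!all(need %in% names(matches)))
    stop_input("matches must have columns: %s", paste(need, collapse = ", "))
  if (any(matches$player_a == matches$player_b))
    stop_input("a player cannot play itself")
  if (!all(matches$score_a %in% c(0, 0.5, 1)))
    stop_input("score_a must be one of 0, 0.5, 1")
  unknown <- setdiff(c(matches$player_a, matches$player_b), states$player)
  if (length(unknown))
    stop_input("match references unknown player(s): %s",
               paste(unknown, collapse = ", "))
  invisible(matches)
}

# Add the period's games to the win/draw/loss tallies.
update_tallies <- function(states, matches) {
  a <- as.character(matches$player_a); b <- as.character(matches$player_b)
  s <- matches$score_a
  who <- c(a, b); sc <- c(s, 1 - s)
  add <- rowsum(cbind(games = rep(1, length(who)),
                      wins = as.numeric(sc == 1),
                      draws = as.numeric(sc == 0.5),
                      losses = as.numeric(sc == 0)),
                group = who)
  i <- match(rownames(add), states$player)
  states$games[i]  <- states$games[i]  + as.integer(add[, "games"])
  states$wins[i]   <- states$wins[i]   + as.integer(add[, "wins"])
  states$draws[i]  <- states$draws[i]  + as.integer(add[, "draws"])
  states$losses[i] <- states$losses[i] + as.integer(add[, "losses"])
  states
}

# Long per-game view: one row per (player, opponent, score) direction.
match_long <- function(states, matches) {
  a <- as.character(matches$player_a); b <- as.character(matches$player_b)
  s <- as.numeric(matches$score_a)
  data.frame(player = c(a, b), opp = c(b, a), score = c(s, 1 - s),
             stringsAsFactors = FALSE)
}
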