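#' Rating-period updates for the four engines
#'
#' Each engine consumes the states at the start of a rating period together
#' with all matches of that period and returns the post-period states. All
#' updates are *batch* (simultaneous): every player's update uses the
#' pre-period ratings and deviations of their opponents, so the result is
#' invariant to the order of matches within the period.
#'
#' `elo_update_period()` moves each rating by K times the summed gap
#' between observed and expected score; deviations and volatilities are
#' untouched.
#'
#' `glicko_update_period()` first inflates every deviation to
#' `min(sqrt(RD^2 + c^2), cap)` (the passage of one period increases
#' uncertainty for everyone, idle players included), then applies the
#' Glicko update: the deviation-damped expected score, the period
#' information `1/d^2`, and the precision-weighted rating step.
#'
#' `glicko2_update_period()` works on the Glicko-2 internal scale
#' (`mu = (r - initial_rating)/(scale/ln(base))`), solves for the new
#' volatility with the bracketed Illinois iteration (tolerance 1e-6, at
#' most 100 iterations), and converts back. Idle players keep their rating
#' and volatility while the deviation grows through sigma.
#'
#' `stephenson_update_period()` is the Glicko update augmented with a
#' per-game addition `h` to the prior rating variance, a per-game bonus
#' `b` added to the rating, and a pull of `lambda` percent toward the mean
#' pre-period opponent rating. With `h = b = lambda = 0` it reproduces
#' `glicko_update_period()` exactly.
#'
#' @param states A [player_states()] data frame (pre-period).
#' @param matches Data frame with columns `player_a`, `player_b`,
#'   `score_a` (0, 0.5 or 1, from player_a's side), all belonging to one
#'   rating period.
#' @param config A [rating_config()].
#' @return The post-period `player_states` data frame (same row order).
#' @seealso [rate_players()] for running whole match logs over many
#'   periods.
#' @name rating-engines
NULL

#' @rdname rating-engines
#' @export
elo_update_period <- function(states, matches, config = rating_config("elo")) {
  validate_states(states)
  if (nrow(matches) == 0L) return(states)
  check_matches(states, matches)
  long <- match_long(states, matches)
  i <- match(long$player, states$player)
  j <- match(long$opp, states$player)
  e <- expected_score(states$rating[i], states$rating[j], config)
  delta <- rowsum(config$k_factor * (long$score - e), group = long$player)
  k <- match(rownames(delta), states$player)
  states$rating[k] <- states$rating[k] + delta[, 1L]
  update_tallies(states, matches)
}

# Shared Glicko-style core. h_total: per-player addition to the prior
# rating variance (Stephenson's h * games; 0 for plain Glicko).
glicko_core <- function(states, matches, config, h_per_game = 0) {
  validate_states(states)
  # onset inflation for everyone, capped
  states$deviation <- pmin(sqrt(states$deviation^2 + config$c_inflation^2),
                           config$deviation_cap)
  if (nrow(matches) == 0L) return(states)
  check_matches(states, matches)
  q <- log(config$logistic_base) / config$logistic_scale
  long <- match_long(states, matches)
  i <- match(long$player, states$player)
  j <- match(long$opp, states$player)
  r <- states$rating[i]; ro <- states$rating[j]; rdo <- states$deviation[j]
  g <- 1 / sqrt(1 + 3 * (q * rdo / pi)^2)
  e <- 1 / (1 + config$logistic_base ^ (-g * (r - ro) / config$logistic_scale))
  agg <- rowsum(cbind(info = g^2 * e * (1 - e),
                      step = g * (long$score - e),
                      opp  = ro,
                      m    = 1),
                group = long$player)
  k <- match(rownames(agg), states$player)
  m <- agg[, "m"]
  rd2 <- states$deviation[k]^2 + h_per_game * m
  d2_inv <- q^2 * agg[, "info"]
  prec <- 1 / rd2 + d2_inv
  states$rating[k] <- states$rating[k] + (q / prec) * agg[, "step"]
  states$deviation[k] <- sqrt(1 / prec)
  attr(states, "period_played") <- stats::setNames(m, rownames(agg))
  attr(states, "period_opp_mean") <- stats::setNames(agg[, "opp"] / m, rownames(agg))
  states
}

#' @rdname rating-engines
#' @export
glicko_update_period <- function(states, matches, config = rating_config("glicko")) {
  out <- glicko_core(states, matches, config, h_per_game = 0)
  attr(out, "period_played") <- NULL
  attr(out, "period_opp_mean") <- NULL
  if (nrow(matches)) out <- update_tallies(out, matches)
  out
}

#' @rdname rating-engines
#' @export
stephenson_update_period <- function(states, matches,
                                     config = rating_config("stephenson")) {
  pre_rating <- stats::setNames(states$rating, states$player)
  out <- glicko_core(states, matches, config, h_per_game = config$h_param)
  played <- attr(out, "period_played")
  opp_mean <- attr(out, "period_opp_mean")
  attr(out, "period_played") <- NULL
  attr(out, "period_opp_mean") <- NULL
  if (!is.null(played)) {
    k <- match(names(played), out$player)
    out$rating[k] <- out$rating[k] + config$b_param * played +
      (config$lambda_param / 100) * (opp_mean - pre_rating[names(played)])
  }
  if (nrow(matches)) out <- update_tallies(out, matches)
  out
}

#' @rdname rating-engines
#' @export
glicko2_update_period <- function(states, matches,
                                  config = rating_config("glicko2")) {
  validate_states(states)
  conv <- config$logistic_scale / log(config$logistic_base)  # 173.7178 for 400/10
  mu <- (states$rating - config$initial_rating) / conv
  phi <- states$deviation / conv
  sig <- states$volatility
  if (nrow(matches)) {
    check_matches(states, matches)
    long <- match_long(states, matches)
    i <- match(long$player, states$player)
    j <- match(long$opp, states$player)
    g <- 1 / sqrt(1 + 3 * phi[j]^2 / pi^2)
    e <- 1 / (1 + exp(-g * (mu[i] - mu[j])))
    agg <- rowsum(cbind(info = g^2 * e * (1 - e),
                        step = g * (long$score - e)),
                  group = long$player)
    k <- match(rownames(agg), states$player)
    v <- 1 / agg[, "info"]
    delta <- v * agg[, "step"]
    sig_new <- mapply(solve_volatility, delta, phi[k], v, sig[k],
                      MoreArgs = list(tau = config$tau))
    phi_star <- sqrt(phi[k]^2 + sig_new^2)
    phi_new <- 1 / sqrt(1 / phi_star^2 + 1 / v)
    mu_new <- mu[k] + phi_new^2 * agg[, "step"]
    mu[k] <- mu_new; phi[k] <- phi_new; sig[k] <- sig_new
    idle <- setdiff(seq_len(nrow(states)), k)
  } else {
    idle <- seq_len(nrow(states))
  }
  if (length(idle)) phi[idle] <- sqrt(phi[idle]^2 + sig[idle]^2)
  states$rating <- config$initial_rating + conv * mu
  states$deviation <- pmin(conv * phi, config$deviation_cap)
  states$volatility <- sig
  if (nrow(matches)) states <- update_tallies(states, matches)
  states
}

# Glicko-2 volatility iteration (Illinois variant of regula falsi) on
# x = ln(sigma^2); tolerance 1e-6, hard cap of 100 iterations.
solve_volatility <- function(delta, phi, v, sigma, tau,
                             tol = 1e-6, max_iter = 100L) {
  a <- log(sigma^2)
  f <- function(x) {
    ex <- exp(x)
    ex * (delta^2 - phi^2 - v - ex) / (2 * (phi^2 + v + ex)^2) - (x - a) / tau^2
  }
  A <- a
  if (delta^2 > phi^2 + v) {
    B <- log(delta^2 - phi^2 - v)
  } else {
    k <- 1
    while (f(a - k * tau) < 0) {
      k <- k + 1
      if (k > max_iter)
        stop_numeric("volatility bracket search failed",
                     diagnostics = list(delta = delta, phi = phi, v = v,
                                        sigma = sigma, tau = tau))
    }
    B <- a - k * tau
  }
  fA <- f(A); fB <- f(B)
  iter <- 0L
  while (abs(B - A) > tol) {
    iter <- iter + 1L
    if (iter > max_iter)
      stop_numeric("volatility solver did not converge in %d iterations",
                   max_iter,
                   diagnostics = list(A = A, B = B, fA = fA, fB = fB,
                                      delta = delta, phi = phi, v = v))
    C <- A + (A - B) * fA / (fB - fA)
    fC <- f(C)
    if (fC * fB <= 0) {
      A <- B; fA <- fB
    } else {
      fA <- fA / 2
    }
    B <- C; fB <- fC
  }
  exp(A / 2)
}
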