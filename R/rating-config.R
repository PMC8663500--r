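#' Configuration for a rating engine
#'
#' Bundles every tunable of the four supported paired-comparison rating
#' systems. The defaults are the conventional ones for Elo-family systems on
#' the chess-like scale: new players start at rating 2200 with deviation 300,
#' the expected score is the base-10 logistic with scale 400, Elo uses
#' K = 27, Glicko inflates idle deviations with c = 15 (capped at 350),
#' Glicko-2 starts volatility at 0.06 with tau = 0.5, and Stephenson adds
#' per-game deviation growth h = 10, no activity bonus, and a 2% pull toward
#' the mean opponent rating.
#'
#' @param system One of `"elo"`, `"glicko"`, `"glicko2"`, `"stephenson"`.
#' @param initial_rating Rating assigned to a player on first appearance.
#' @param initial_deviation Rating deviation (RD) on first appearance
#'   (rating points); ignored by plain Elo.
#' @param initial_volatility Glicko-2 volatility sigma on first appearance.
#' @param k_factor Elo K: rating points moved per unit of (observed -
#'   expected) score.
#' @param c_inflation Glicko/Stephenson idle-deviation growth c: at the
#'   onset of each rating period every known player's RD becomes
#'   `min(sqrt(RD^2 + c^2), deviation_cap)`.
#' @param tau Glicko-2 volatility constraint; smaller values restrain
#'   volatility changes.
#' @param h_param Stephenson per-game addition to the rating variance.
#' @param b_param Stephenson per-game rating bonus for playing.
#' @param lambda_param Stephenson pull (percent) of the rating toward the
#'   mean pre-period opponent rating.
#' @param deviation_cap Upper bound on any rating deviation.
#' @param logistic_scale,logistic_base Scale and base of the expected-score
#'   logistic; defaults 400 and 10.
#'
#' @return An object of class `"rating_config"` (a named list).
#' @examples
#' rating_config("glicko")
#' rating_config("elo", k_factor = 32)
#' @export
rating_config <- function(system = c("glicko", "elo", "glicko2", "stephenson"),
                          initial_rating = 2200,
                          initial_deviation = 300,
                          initial_volatility = 0.06,
                          k_factor = 27,
                          c_inflation = 15,
                          tau = 0.5,
                          h_param = 10,
                          b_param = 0,
                          lambda_param = 2,
                          deviation_cap = 350,
                          logistic_scale = 400,
                          logistic_base = 10) {
  system <- match.arg(system)
  num1 <- function(x, nm, positive = TRUE, nonneg = FALSE) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
      stop_input("'%s' must be a single finite number", nm)
    if (positive && x <= 0) stop_input("'%s' must be > 0", nm)
    if (nonneg && x < 0) stop_input("'%s' must be >= 0", nm)
    as.numeric(x)
  }
  cfg <- list(
    system             = system,
    initial_rating     = num1(initial_rating, "initial_rating", positive = FALSE),
    initial_deviation  = num1(initial_deviation, "initial_deviation"),
    initial_volatility = num1(initial_volatility, "initial_volatility"),
    k_factor           = num1(k_factor, "k_factor"),
    c_inflation        = num1(c_inflation, "c_inflation", positive = FALSE, nonneg = TRUE),
    tau                = num1(tau, "tau"),
    h_param            = num1(h_param, "h_param", positive = FALSE, nonneg = TRUE),
    b_param            = num1(b_param, "b_param", positive = FALSE, nonneg = TRUE),
    lambda_param       = num1(lambda_param, "lambda_param", positive = FALSE, nonneg = TRUE),
    deviation_cap      = num1(deviation_cap, "deviation_cap"),
    logistic_scale     = num1(logistic_scale, "logistic_scale"),
    logistic_base      = num1(logistic_base, "logistic_base")
  )
  if (cfg$initial_deviation > cfg$deviation_cap)
    stop_input("initial_deviation (%g) exceeds deviation_cap (%g)",
               cfg$initial_deviation, cfg$deviation_cap)
  structure(cfg, class = "rating_config")
}

#' @export
print.rating_config <- function(x, ...) {
  cat("Rating configuration (", x$system, ")\n", sep = "")
  flds <- setdiff(names(x), "system")
  for (f in flds) cat(sprintf("  %-18s %g\n", f, x[[f]]))
  invisible(x)
}

#' Expected score of one player against another
#'
#' The probability that the first player beats the second under the logistic
#' paired-comparison (Bradley-Terry type) model
#' \eqn{E = 1 / (1 + b^{(r_2 - r_1)/s})} with base \eqn{b} and scale
#' \eqn{s} taken from the configuration (defaults: base 10, scale 400, so a
#' 400-point advantage gives expected score 10/11).
#'
#' @param rating_a,rating_b Ratings of the two players; vectors recycle.
#' @param config A [rating_config()].
#' @return Expected score(s) strictly in (0, 1); `expected_score(a, b) +
#'   expected_score(b, a)` is always 1.
#' @examples
#' expected_score(2200, 2200)  # 0.5
#' expected_score(2400, 2000)  # 10/11
#' @export
expected_score <- function(rating_a, rating_b, config = rating_config()) {
  if (!is.numeric(rating_a) || !is.numeric(rating_b) ||
      any(!is.finite(rating_a)) || any(!is.finite(rating_b)))
    stop_input("ratings must be finite numbers")
  1 / (1 + config$logistic_base ^ ((rating_b - rating_a) / config$logistic_scale))
}
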