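test_that("expected score follows the base-10 scale-400 logistic and normalizes", {
  cfg <- rating_config("elo")
  expect_equal(expected_score(2200, 2200, cfg), 0.5)
  expect_equal(expected_score(2400, 2000, cfg), 10 / 11)
  expect_equal(expected_score(2000, 2400, cfg), 1 / 11)
  # normalization over random rating pairs
  set.seed(11)
  a <- runif(200, 1000, 3000); b <- runif(200, 1000, 3000)
  expect_equal(expected_score(a, b, cfg) + expected_score(b, a, cfg),
               rep(1, 200))
  expect_true(all(expected_score(a, b, cfg) > 0 & expected_score(a, b, cfg) < 1))
  expect_error(expected_score(Inf, 2200, cfg), class = "rehabElo_input_error")
})

test_that("Elo period update moves ratings by K * (score - expected)", {
  cfg <- rating_config("elo", k_factor = 32)
  st <- player_states(c("A", "B"), cfg)
  m <- data.frame(period = 1, player_a = "A", player_b = "B", score_a = 1)
  out <- elo_update_period(st, m, cfg)
  expect_equal(out$rating, c(2216, 2184))
  expect_equal(out$wins, c(1L, 0L))
  # draw between equals leaves both unchanged
  m$score_a <- 0.5
  out <- elo_update_period(st, m, cfg)
  expect_equal(out$rating, c(2200, 2200))
  # hand-computed asymmetric case: 2200 beats 2000 at K = 20
  cfg20 <- rating_config("elo", k_factor = 20)
  st2 <- player_states(c("A", "B"), cfg20, rating = c(2200, 2000))
  m2 <- data.frame(period = 1, player_a = "A", player_b = "B", score_a = 1)
  out2 <- elo_update_period(st2, m2, cfg20)
  gain <- 20 * (1 - 1 / (1 + 10^((2000 - 2200) / 400)))
  expect_equal(out2$rating[1], 2200 + gain)
  expect_equal(out2$rating[2], 2000 - gain)
  expect_error(
    elo_update_period(st, data.frame(period = 1, player_a = "A",
                                     player_b = "Z", score_a = 1), cfg),
    class = "rehabElo_input_error")
})

test_that("Elo rating changes sum to zero within a period (conservation)", {
  cfg <- rating_config("elo", k_factor = 27)
  set.seed(3)
  players <- paste0("p", 1:8)
  st <- player_states(players, cfg, rating = runif(8, 1800, 2600))
  m <- data.frame(period = 1,
                  player_a = sample(players, 30, replace = TRUE),
                  player_b = sample(players, 30, replace = TRUE),
                  score_a = sample(c(0, 0.5, 1), 30, replace = TRUE))
  m <- m[m$player_a != m$player_b, ]
  out <- elo_update_period(st, m, cfg)
  expect_equal(sum(out$rating - st$rating), 0, tolerance = 1e-9)
})

test_that("Glicko update matches the published worked example", {
  wx <- worked_example("glicko")
  out <- glicko_update_period(wx$states, wx$matches, wx$cfg)
  p <- out[out$player == "P", ]
  expect_equal(p$rating, 1464, tolerance = 0.5 / 1464)
  expect_equal(p$deviation, 151.4, tolerance = 0.5 / 151.4)
  # one game tallied per match on each side
  expect_equal(out$games, c(3L, 1L, 1L, 1L))
})

test_that("Glicko deviation shrinks with play and inflates when idle", {
  cfg <- rating_config("glicko", c_inflation = 15)
  st <- player_states(c("A", "B", "Idle"), cfg)
  m <- data.frame(period = 1, player_a = "A", player_b = "B", score_a = 1)
  out <- glicko_update_period(st, m, cfg)
  pre_inflated <- min(sqrt(300^2 + 15^2), cfg$deviation_cap)
  expect_lt(out$deviation[out$player == "A"], pre_inflated)
  expect_lt(out$deviation[out$player == "B"], pre_inflated)
  expect_equal(out$deviation[out$player == "Idle"], pre_inflated)
  expect_equal(out$rating[out$player == "Idle"], 2200)
  # c = 0: idle player exactly unchanged
  cfg0 <- rating_config("glicko", c_inflation = 0)
  out0 <- glicko_update_period(player_states(c("A", "B", "Idle"), cfg0), m, cfg0)
  expect_equal(out0$rating[out0$player == "Idle"], 2200)
  expect_equal(out0$deviation[out0$player == "Idle"], 300)
  # the cap binds
  cfg_cap <- rating_config("glicko", c_inflation = 200, deviation_cap = 320)
  outc <- glicko_update_period(player_states("Z", cfg_cap),
                               data.frame(), cfg_cap)
  expect_equal(outc$deviation, 320)
})

test_that("Glicko-2 update matches the published worked example", {
  wx <- worked_example("glicko2")
  out <- glicko2_update_period(wx$states, wx$matches, wx$cfg)
  p <- out[out$player == "P", ]
  expect_equal(p$rating, 1464.06, tolerance = 0.5 / 1464)
  expect_equal(p$deviation, 151.52, tolerance = 0.5 / 151.5)
  expect_equal(p$volatility, 0.05999, tolerance = 1e-3)
})

test_that("Glicko-2 idle players keep rating, deviation grows through sigma", {
  cfg <- rating_config("glicko2", initial_deviation = 200)
  st <- player_states("Solo", cfg)
  out <- glicko2_update_period(st, data.frame(), cfg)
  conv <- 400 / log(10)
  phi <- 200 / conv
  expect_equal(out$rating, 2200)
  expect_equal(out$deviation, conv * sqrt(phi^2 + 0.06^2))
  expect_equal(out$volatility, 0.06)
})

test_that("Glicko-2 single-match win and loss displace the rating symmetrically", {
  cfg <- rating_config("glicko2")
  run1 <- function(score) {
    st <- player_states(c("A", "B"), cfg)
    m <- data.frame(period = 1, player_a = "A", player_b = "B",
                    score_a = score)
    out <- glicko2_update_period(st, m, cfg)
    out$rating[out$player == "A"] - 2200
  }
  expect_equal(run1(1), -run1(0), tolerance = 1e-9)
})

test_that("Stephenson with zeroed extras reproduces Glicko exactly", {
  wx <- worked_example("glicko")
  cfg_s <- rating_config("stephenson", initial_rating = 1500,
                         initial_deviation = 350, c_inflation = 0,
                         h_param = 0, b_param = 0, lambda_param = 0)
  g <- glicko_update_period(wx$states, wx$matches, wx$cfg)
  s <- stephenson_update_period(wx$states, wx$matches, cfg_s)
  expect_equal(s$rating, g$rating, tolerance = 1e-9)
  expect_equal(s$deviation, g$deviation, tolerance = 1e-9)
})

test_that("Stephenson bonus raises the rating of an all-drawing player", {
  cfg_b <- rating_config("stephenson", h_param = 0, b_param = 5,
                         lambda_param = 0, c_inflation = 0)
  cfg_0 <- rating_config("stephenson", h_param = 0, b_param = 0,
                         lambda_param = 0, c_inflation = 0)
  st <- player_states(c("A", "B"), cfg_b)
  m <- data.frame(period = 1, player_a = "A", player_b = "B",
                  score_a = rep(0.5, 4))
  with_bonus <- stephenson_update_period(st, m, cfg_b)
  without <- stephenson_update_period(st, m, cfg_0)
  expect_gt(with_bonus$rating[1], without$rating[1])
  expect_equal(without$rating[1], 2200)  # equal draws move nothing
  # lambda with no games played leaves the rating untouched
  cfg_l <- rating_config("stephenson", lambda_param = 50, c_inflation = 0)
  idle <- stephenson_update_period(player_states("Z", cfg_l),
                                   m[0, ], cfg_l)
  expect_equal(idle$rating, 2200)
})

test_that("a win never yields a lower rating than a draw, nor a draw than a loss", {
  for (sys in c("elo", "glicko", "glicko2", "stephenson")) {
    cfg <- if (sys == "stephenson")
      rating_config(sys, lambda_param = 0) else rating_config(sys)
    after <- vapply(c(0, 0.5, 1), function(s) {
      st <- player_states(c("A", "B"), cfg, rating = c(2300, 2100))
      m <- data.frame(period = 1, player_a = "A", player_b = "B", score_a = s)
      f <- switch(sys, elo = elo_update_period, glicko = glicko_update_period,
                  glicko2 = glicko2_update_period,
                  stephenson = stephenson_update_period)
      out <- f(st, m, cfg)
      out$rating[out$player == "A"]
    }, numeric(1))
    expect_true(all(diff(after) > 0), info = sys)
  }
})

test_that("rate_players processes periods in order with batch semantics", {
  cfg <- rating_config("glicko", c_inflation = 0)
  set.seed(21)
  m <- data.frame(period = rep(1:3, each = 6),
                  player_a = sample(paste0("p", 1:4), 18, replace = TRUE),
                  player_b = sample(paste0("p", 1:4), 18, replace = TRUE),
                  score_a = sample(c(0, 0.5, 1), 18, replace = TRUE))
  m <- m[m$player_a != m$player_b, ]
  fit <- rate_players(m, cfg)
  # permuting rows within periods changes nothing
  set.seed(99)
  fit2 <- rate_players(m[sample(nrow(m)), ], cfg)
  expect_equal(leaderboard(fit), leaderboard(fit2))
  # bookkeeping: total games are twice the matches
  expect_equal(sum(leaderboard(fit)$games), 2 * nrow(m))
  expect_equal(fit$periods, 1:3)
  # snapshots are per processed period
  expect_equal(names(fit$snapshots), as.character(1:3))
})

test_that("rate_players with no matches returns initial states", {
  cfg <- rating_config("glicko")
  st <- player_states(c("A", "B"), cfg)
  fit <- rate_players(data.frame(), cfg, initial_states = st)
  expect_equal(nrow(leaderboard(fit)), 2)
  expect_equal(leaderboard(fit)$rating, c(2200, 2200))
  expect_equal(length(fit$snapshots), 0L)
})

test_that("identical records in identical periods yield identical states", {
  # mirrors the two undefeated players sharing one leaderboard row value
  cfg <- rating_config("glicko")
  m <- do.call(rbind, lapply(1:5, function(p)
    data.frame(period = p, player_a = c("T1", "T2"), player_b = "Opp",
               score_a = 1)))
  lb <- leaderboard(rate_players(m, cfg))
  expect_equal(lb$rating[lb$player == "T1"], lb$rating[lb$player == "T2"])
  expect_equal(lb$deviation[lb$player == "T1"],
               lb$deviation[lb$player == "T2"])
})

test_that("leaderboard sorts by rating descending with id tie-break", {
  cfg <- rating_config("elo")
  m <- data.frame(period = 1, player_a = c("b", "a"), player_b = c("z", "y"),
                  score_a = 1)
  lb <- leaderboard(rate_players(m, cfg))
  expect_equal(lb$player, c("a", "b", "y", "z"))
})

test_that("rating_fit methods expose ratings, history, and predictions", {
  cfg <- rating_config("elo", k_factor = 32)
  m <- data.frame(period = 1, player_a = "A", player_b = "B", score_a = 1)
  fit <- rate_players(m, cfg)
  expect_equal(unname(coef(fit)), c(2216, 2184))
  h <- rating_history(fit)
  expect_equal(nrow(h), 2)
  pr <- predict(fit, data.frame(player_a = "A", player_b = "B"))
  expect_equal(pr, expected_score(2216, 2184, cfg))
  expect_output(print(fit), "elo")
  expect_error(predict(fit, data.frame(x = 1)),
               class = "rehabElo_input_error")
})

test_that("volatility solver reports non-convergence with diagnostics", {
  expect_error(rehabElo:::solve_volatility(0.5, 0.2, 1, 0.06, tau = 0.5,
                                           max_iter = 0L),
               class = "rehabElo_numeric_error")
})
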