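# Shared fixtures built in code.

# The published Glicko/Glicko-2 worked example: a 1500-rated player with
# RD 200 facing three opponents (win, loss, loss) in one rating period.
worked_example <- function(system = "glicko", c_inflation = 0) {
  cfg <- rating_config(system, initial_rating = 1500,
                       initial_deviation = 350, c_inflation = c_inflation,
                       tau = 0.5)
  states <- player_states(c("P", "A", "B", "C"), cfg,
                          rating = c(1500, 1400, 1550, 1700),
                          deviation = c(200, 30, 100, 300))
  matches <- data.frame(period = 1,
                        player_a = "P",
                        player_b = c("A", "B", "C"),
                        score_a = c(1, 0, 0))
  list(cfg = cfg, states = states, matches = matches)
}

# Tiny execution table: one patient, explicit results.
mk_executions <- function(results, patient = "p1", task = "tA",
                          level = 1L, session = NULL) {
  n <- length(results)
  data.frame(patient_id = patient, task_id = task,
             difficulty_level = level,
             session_index = if (is.null(session)) seq_len(n) else session,
             execution_index = seq_len(n),
             result = results, stringsAsFactors = FALSE)
}

# Stack executions for several patients.
mk_multi_executions <- function(results_by_patient, ...) {
  do.call(rbind, lapply(names(results_by_patient), function(p)
    mk_executions(results_by_patient[[p]], patient = p, ...)))
}

# Rate a cohort simulation on its first n executions with the cohort
# defaults (Stephenson, per-session periods, task-by-difficulty
# opponents) and return the patient ratings.
early_ratings <- function(sim, n = 50, config = rating_config("stephenson")) {
  ml <- build_match_log(truncate_first_n(sim$executions, n),
                        outcome_rule("cohort"),
                        "per_session", "task_by_difficulty")
  r <- coef(rate_players(ml, config))
  r[intersect(sim$cohort$patient_id, names(r))]
}
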