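#' Stratify patients into rating terciles
#'
#' Splits patients into low / mid / high groups of (near-)equal size by
#' rating rank. When the number of patients is not divisible by three the
#' extra member(s) go to the lowest group(s) first, so sizes differ by at
#' most one. Ties in rating are broken by patient id, making the
#' assignment deterministic; because only ranks are used, any strictly
#' increasing transform of the ratings yields the same stratification.
#'
#' @param ratings Named numeric vector: patient id -> rating.
#' @return Factor (levels `low`, `mid`, `high`) named by patient id.
#' @examples
#' r <- setNames(c(10, 20, 30, 40, 50, 60), paste0("p", 1:6))
#' table(stratify_terciles(r))
#' @export
stratify_terciles <- function(ratings) {
  if (is.null(names(ratings)) || anyDuplicated(names(ratings)))
    stop_input("'ratings' must be named by unique patient ids")
  n <- length(ratings)
  if (n < 3) stop_input("need at least 3 patients to form terciles")
  ord <- order(ratings, names(ratings))  # ascending rating, ties by id
  base <- n %/% 3L
  rem <- n %% 3L
  sizes <- base + c(rem >= 1L, rem >= 2L, 0L)  # extras to low, then mid
  lab <- rep(c("low", "mid", "high"), times = sizes)
  out <- factor(character(n), levels = c("low", "mid", "high"))
  out[ord] <- lab
  names(out) <- names(ratings)
  out
}

#' Improvement flag from admission and discharge scores
#'
#' A patient improved on an instrument when discharge minus admission is
#' at least the instrument's threshold: 5 points for the RAVLT learning
#' total (0-75), 1 point for delayed recall, recognition and digit span.
#'
#' @param admission,discharge Integer score vectors.
#' @param threshold Minimum gain counted as improvement.
#' @return Logical vector.
#' @examples
#' improvement_flags(37, 44, threshold = 5)  # TRUE
#' improvement_flags(40, 44, threshold = 5)  # FALSE
#' @export
improvement_flags <- function(admission, discharge, threshold) {
  if (length(admission) != length(discharge))
    stop_input("admission and discharge must have equal length")
  (discharge - admission) >= threshold
}

#' Cross-tabulation with a chi-square independence test
#'
#' Builds the contingency table of two categorical margins, computes
#' Pearson's chi-square statistic without continuity correction on
#' (r-1)(c-1) degrees of freedom, and row percentages to one decimal.
#'
#' @param groups,outcome Equal-length vectors (coerced to factor).
#' @return Object of class `"crosstab"`: `counts`, `row_pct`,
#'   `chi2_statistic`, `df`, `p_value`.
#' @examples
#' ct <- crosstab(rep(c("a", "b"), each = 25),
#'                rep(c("x", "y", "x", "y"), c(20, 5, 5, 20)))
#' ct$chi2_statistic  # 18 on 1 df
#' @export
crosstab <- function(groups, outcome) {
  g <- factor(groups); o <- factor(outcome)
  if (nlevels(g) < 2 || nlevels(o) < 2)
    stop_input("both margins need at least two levels")
  counts <- table(g, o)
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop_input("empty row or column in contingency table")
  test <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  structure(list(counts = counts,
                 row_pct = round(100 * prop.table(counts, 1), 1),
                 chi2_statistic = unname(test$statistic),
                 df = unname(test$parameter),
                 p_value = unname(test$p.value)),
            class = "crosstab")
}

#' @export
print.crosstab <- function(x, ...) {
  print(x$counts)
  cat(sprintf("Chi-square = %.3f on %d df, p = %.4g\n",
              x$chi2_statistic, x$df, x$p_value))
  invisible(x)
}

#' Per-tercile cohort summary
#'
#' Summarises a cohort by rating group the way stratified rehabilitation
#' reports are laid out: means and SDs of the memory assessments at
#' admission and discharge, proportions of patients that improved on each
#' instrument, mean number of executed tasks and mean obtained result, and
#' the distribution of executed task difficulty levels. Continuous rows
#' carry a one-way ANOVA p-value; binary/categorical rows a chi-square
#' p-value.
#'
#' @param cohort Cohort data frame (see [generate_cohort()] for the
#'   column layout) with an `elo_group` column (factor low/mid/high).
#' @param executions Optional execution data frame used for the
#'   executed-tasks, mean-result and difficulty rows.
#' @return Object of class `"cohort_summary"`: a data frame `stats` (one
#'   row per variable: per-group value, p-value, test used) plus the
#'   difficulty `crosstab` when executions are given.
#' @export
group_summary <- function(cohort, executions = NULL) {
  if (!"elo_group" %in% names(cohort))
    stop_input("cohort must carry an 'elo_group' column; run stratify_terciles() first")
  g <- factor(cohort$elo_group, levels = c("low", "mid", "high"))
  g <- droplevels(g)
  if (nlevels(g) < 2) stop_input("need at least two rating groups to compare")

  cont_row <- function(x, label) {
    ok <- is.finite(x)
    p <- tryCatch(summary(stats::aov(x[ok] ~ g[ok]))[[1]][["Pr(>F)"]][1],
                  error = function(e) NA_real_)
    vals <- tapply(x[ok], g[ok], function(v)
      sprintf("%.1f (%.1f)", mean(v), stats::sd(v)))
    data.frame(variable = label, t(vals), p_value = p, test = "anova",
               stringsAsFactors = FALSE, check.names = FALSE)
  }
  prop_row <- function(flag, label) {
    ok <- !is.na(flag)
    ct <- tryCatch(crosstab(g[ok], flag[ok]), error = function(e) NULL)
    vals <- tapply(flag[ok], g[ok], function(v)
      sprintf("%d (%.1f%%)", sum(v), 100 * mean(v)))
    data.frame(variable = label, t(vals),
               p_value = if (is.null(ct)) NA_real_ else ct$p_value,
               test = "chi-square", stringsAsFactors = FALSE,
               check.names = FALSE)
  }

  rows <- list()
  score_vars <- list(
    c("digits_adm", "DIGITS at admission"),
    c("ravlt075_adm", "RAVLT075 at admission"),
    c("ravlt015_adm", "RAVLT015 at admission"),
    c("ravlt015r_adm", "RAVLT015R at admission"),
    c("digits_dis", "DIGITS at discharge"),
    c("ravlt075_dis", "RAVLT075 at discharge"),
    c("ravlt015_dis", "RAVLT015 at discharge"),
    c("ravlt015r_dis", "RAVLT015R at discharge"),
    c("age_years", "Age (years)"),
    c("length_of_stay_days", "Length of stay (days)"))
  for (v in score_vars)
    if (v[1] %in% names(cohort)) rows[[v[2]]] <- cont_row(cohort[[v[1]]], v[2])

  imp_defs <- list(c("ravlt075", "RAVLT075 improved", 5),
                   c("ravlt015", "RAVLT015 improved", 1),
                   c("ravlt015r", "RAVLT015R improved", 1),
                   c("digits", "DIGITS improved", 1))
  for (d in imp_defs) {
    adm <- paste0(d[1], "_adm"); dis <- paste0(d[1], "_dis")
    if (all(c(adm, dis) %in% names(cohort))) {
      fl <- improvement_flags(cohort[[adm]], cohort[[dis]], as.numeric(d[3]))
      rows[[d[2]]] <- prop_row(fl, d[2])
    }
  }

  difficulty_ct <- NULL
  if (!is.null(executions)) {
    validate_executions(executions)
    ex_group <- g[match(executions$patient_id, cohort$patient_id)]
    ok <- !is.na(ex_group)
    rows[["Executed tasks (mean per patient)"]] <- {
      per_pat <- table(executions$patient_id[ok])
      x <- as.numeric(per_pat[match(cohort$patient_id, names(per_pat))])
      x[is.na(x)] <- 0
      cont_row(x, "Executed tasks (mean per patient)")
    }
    rows[["Obtained results in tasks"]] <- {
      per_pat_mean <- tapply(executions$result[ok], executions$patient_id[ok], mean)
      x <- as.numeric(per_pat_mean[match(cohort$patient_id, names(per_pat_mean))])
      cont_row(x, "Obtained results in tasks")
    }
    difficulty_ct <- crosstab(ex_group[ok], executions$difficulty_level[ok])
  }

  stats_df <- do.call(rbind, rows)
  rownames(stats_df) <- NULL
  structure(list(stats = stats_df, difficulty = difficulty_ct,
                 group_sizes = table(g)),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("Cohort summary by rating group (n = ",
      paste(x$group_sizes, collapse = "/"), ")\n", sep = "")
  df <- x$stats
  df$p_value <- signif(df$p_value, 3)
  print(df, row.names = FALSE)
  if (!is.null(x$difficulty)) {
    cat("\nTask difficulty level by group:\n")
    print(x$difficulty)
  }
  invisible(x)
}
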