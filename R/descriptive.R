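#' Round half away from zero
#'
#' Display rounding used by the descriptive and life-table reports (the
#' usual epidemiological convention: one decimal for percentages, two for
#' years). Internal computation always keeps full precision.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

descriptive_variables <- function() {
  c("education", "marital", "smoking", "drinking", "expenses", "medical",
    "exercise", "diabetes", "heart_disease", "stroke")
}

#' Stratified descriptive summary of a cohort
#'
#' Summarises the cohort by region-by-sex stratum: subject count, mean and
#' SD of entry age, and for each baseline categorical variable (plus the
#' disability state at entry) the level counts and percentages. Percentages
#' use the nonmissing denominator within the stratum and are reported with
#' the one-decimal display convention; `pct_raw` keeps full precision.
#'
#' @param cohort an `eldercohort`.
#' @return A data frame with columns `region`, `sex`, `variable`, `level`,
#'   `n`, `pct`, `pct_raw`, `mean`, `sd`. Rows with `variable == "n"` carry
#'   the stratum size; `variable == "entry_age"` carries mean/SD; empty
#'   strata yield `n = 0` rows without error.
#' @export
descriptive_table <- function(cohort) {
  stopifnot(inherits(cohort, "eldercohort"), n_subjects(cohort) > 0)
  subj <- cohort$subjects
  first_obs <- cohort$observations[order(cohort$observations$id,
                                         cohort$observations$age), ]
  first_obs <- first_obs[!duplicated(first_obs$id), ]
  subj$entry_state <- first_obs$state[match(subj$id, first_obs$id)]
  lev <- covariate_levels()
  state_lev <- c("no_disability", "mild_disability", "severe_disability")

  out <- list()
  add <- function(region, sex, variable, level, n, pct_raw = NA_real_,
                  mean = NA_real_, sd = NA_real_) {
    out[[length(out) + 1L]] <<- data.frame(
      region = region, sex = sex, variable = variable, level = level,
      n = n, pct = round_half_up(pct_raw, 1), pct_raw = pct_raw,
      mean = mean, sd = sd, stringsAsFactors = FALSE)
  }

  for (region in c("urban", "rural")) {
    for (sex in c("male", "female")) {
      s <- subj[!is.na(subj$region) & subj$region == region &
                  !is.na(subj$sex) & subj$sex == sex, , drop = FALSE]
      add(region, sex, "n", "", nrow(s))
      if (nrow(s) > 0) {
        add(region, sex, "entry_age", "", nrow(s),
            mean = mean(s$entry_age), sd = stats::sd(s$entry_age))
      } else {
        add(region, sex, "entry_age", "", 0L)
      }
      vars <- c(descriptive_variables(), "entry_state")
      for (v in vars) {
        vals <- if (v == "entry_state") state_lev[s$entry_state + 1L] else s[[v]]
        levels_v <- if (v == "entry_state") state_lev else lev[[v]]
        denom <- sum(!is.na(vals))
        for (l in levels_v) {
          cnt <- sum(!is.na(vals) & vals == l)
          pct <- if (denom > 0) 100 * cnt / denom else NA_real_
          add(region, sex, v, l, cnt, pct)
        }
      }
    }
  }
  do.call(rbind, out)
}

#' Render a descriptive table as aligned text
#'
#' @param tab output of [descriptive_table()].
#' @return Character vector of report lines, invisibly; also printed.
#' @export
format_descriptive <- function(tab) {
  lines <- character()
  for (region in unique(tab$region)) {
    for (sex in unique(tab$sex[tab$region == region])) {
      t <- tab[tab$region == region & tab$sex == sex, ]
      n_row <- t[t$variable == "n", ]
      age_row <- t[t$variable == "entry_age", ]
      lines <- c(lines, sprintf("== %s %s (N=%d) ==", region, sex, n_row$n[1]))
      if (!is.na(age_row$mean[1])) {
        lines <- c(lines, sprintf("  entry age: %.1f +/- %.1f",
                                  age_row$mean[1], age_row$sd[1]))
      }
      cats <- t[!(t$variable %in% c("n", "entry_age")), ]
      for (i in seq_len(nrow(cats))) {
        lines <- c(lines, sprintf("  %-14s %-18s %6d (%s)",
                                  cats$variable[i], cats$level[i], cats$n[i],
                                  ifelse(is.na(cats$pct[i]), "--",
                                         sprintf("%.1f", cats$pct[i]))))
      }
    }
  }
  cat(lines, sep = "\n")
  invisible(lines)
}
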