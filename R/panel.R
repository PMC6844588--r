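#' Baseline covariate columns and their category levels
#'
#' The covariates carried by a cohort: sex, region, marital status,
#' education, living expenses, medical service, smoking, drinking,
#' exercise, diabetes, heart disease and stroke. The first level of each
#' factor in [covariate_levels()] is the reference category used by the
#' onset hazard models.
#'
#' @return `covariate_columns()`: character vector of column names;
#'   `covariate_levels()`: named list of category levels.
#' @export
covariate_columns <- function() {
  c("sex", "region", "marital", "education", "expenses", "medical",
    "smoking", "drinking", "exercise", "diabetes", "heart_disease", "stroke")
}

#' @rdname covariate_columns
#' @export
covariate_levels <- function() {
  list(
    sex = c("male", "female"),
    region = c("urban", "rural"),
    marital = c("others", "married"),
    education = c("0y", "1-6y", "7+y"),
    expenses = c("insufficient", "sufficient"),
    medical = c("inadequate", "adequate"),
    smoking = c("no", "yes"),
    drinking = c("no", "yes"),
    exercise = c("no", "yes"),
    diabetes = c("no", "yes"),
    heart_disease = c("no", "yes"),
    stroke = c("no", "yes")
  )
}

#' One subject's observation history
#'
#' Bundles a subject's ordered interview ages, the living states observed at
#' those ages, an exactly known death age when the subject died before the
#' next scheduled contact, and baseline covariates. Invariants are enforced:
#' strictly increasing ages, states in \{0, 1, 2\}, death strictly after the
#' last living observation, and at least two information points (two
#' observations, or one observation plus a death).
#'
#' @param id subject identifier (coerced to character).
#' @param obs_ages numeric vector of interview ages in years.
#' @param obs_states integer vector of living state codes (0/1/2).
#' @param death_age death age in years, or `NA` if not observed dead.
#' @param covariates named list of baseline covariates (see
#'   [covariate_columns()] for the recognised names); missing values are kept
#'   as `NA`, never defaulted.
#' @return An object of class `subject_history`.
#' @export
subject_history <- function(id, obs_ages, obs_states, death_age = NA_real_,
                            covariates = list()) {
  if (length(obs_ages) != length(obs_states)) {
    stop("obs_ages and obs_states must have equal length")
  }
  if (length(obs_ages) == 0L) stop("subject has no observations")
  if (any(diff(obs_ages) <= 0)) {
    stop("obs_ages must be strictly increasing for subject ", id)
  }
  if (!all(obs_states %in% 0:2)) {
    stop("obs_states must be living state codes 0/1/2 for subject ", id)
  }
  has_death <- length(death_age) == 1L && !is.na(death_age)
  if (has_death && death_age <= obs_ages[length(obs_ages)]) {
    stop("death age must exceed the last observation age for subject ", id)
  }
  if (length(obs_ages) + has_death < 2L) {
    stop("subject ", id, " has fewer than 2 information points")
  }
  structure(
    list(id = as.character(id), obs_ages = as.numeric(obs_ages),
         obs_states = as.integer(obs_states),
         death_age = if (has_death) as.numeric(death_age) else NA_real_,
         covariates = covariates),
    class = "subject_history"
  )
}

new_cohort <- function(subjects, observations, excluded = NULL) {
  if (is.null(excluded)) {
    excluded <- data.frame(id = character(), reason = character(),
                           stringsAsFactors = FALSE)
  }
  rownames(subjects) <- NULL
  rownames(observations) <- NULL
  structure(list(subjects = subjects, observations = observations,
                 excluded = excluded),
            class = "eldercohort")
}

#' @export
print.eldercohort <- function(x, ...) {
  cat("Elderly panel cohort\n")
  cat("  subjects:     ", nrow(x$subjects), "\n")
  cat("  observations: ", nrow(x$observations), "\n")
  cat("  deaths:       ", sum(!is.na(x$subjects$death_age)), "\n")
  if (nrow(x$excluded) > 0) {
    cat("  excluded:     ", nrow(x$excluded), "subject(s) --",
        paste(unique(x$excluded$reason), collapse = "; "), "\n")
  }
  invisible(x)
}

#' Number of subjects in a cohort
#' @param cohort an `eldercohort` object.
#' @return Integer count of retained subjects.
#' @export
n_subjects <- function(cohort) nrow(cohort$subjects)

#' Assemble a cohort from subject histories
#'
#' @param histories list of [subject_history()] objects.
#' @return An `eldercohort` holding a subjects table (one row per subject:
#'   id, entry age, death age, covariates) and a long observations table
#'   (id, age, state).
#' @export
make_cohort <- function(histories) {
  stopifnot(length(histories) > 0)
  covs <- covariate_columns()
  subj <- do.call(rbind, lapply(histories, function(h) {
    row <- data.frame(id = h$id, entry_age = h$obs_ages[1],
                      death_age = h$death_age, stringsAsFactors = FALSE)
    for (v in covs) {
      val <- h$covariates[[v]]
      row[[v]] <- if (is.null(val)) NA_character_ else as.character(val)
    }
    row
  }))
  obs <- do.call(rbind, lapply(histories, function(h) {
    data.frame(id = h$id, age = h$obs_ages, state = h$obs_states,
               stringsAsFactors = FALSE)
  }))
  new_cohort(subj, obs)
}

#' Extract one subject's history from a cohort
#' @param cohort an `eldercohort`.
#' @param id subject identifier.
#' @return A [subject_history()] object.
#' @export
get_subject <- function(cohort, id) {
  srow <- cohort$subjects[cohort$subjects$id == id, , drop = FALSE]
  if (nrow(srow) == 0L) stop("no subject with id ", id)
  orow <- cohort$observations[cohort$observations$id == id, , drop = FALSE]
  orow <- orow[order(orow$age), , drop = FALSE]
  covs <- as.list(srow[1, covariate_columns(), drop = FALSE])
  subject_history(id, orow$age, orow$state, srow$death_age[1], covs)
}

default_panel_mapping <- function() {
  cols <- c("subject_id", "age", "state", "death_age", covariate_columns())
  stats::setNames(cols, cols)
}

#' Read a long-format panel CSV into a validated cohort
#'
#' Expects one row per subject-wave with a subject id, the interview age in
#' years, the observed living state (0/1/2), an optional exact death age
#' (repeated or given on any of the subject's rows), and baseline
#' covariates. Column names can be remapped through `mapping`.
#'
#' Validation follows the panel-design contract: an unknown state code or a
#' death age at or before the last interview is a hard error naming the
#' offending rows; subjects with non-monotone interview ages, or with fewer
#' than two information points (a single interview and no death, i.e. lost
#' before their first follow-up), are excluded and reported in the cohort's
#' `excluded` table rather than silently dropped.
#'
#' @param path CSV file path.
#' @param mapping named character vector mapping canonical column names
#'   (`subject_id`, `age`, `state`, `death_age`, covariates) to the file's
#'   column names; defaults to identity. Covariate columns absent from the
#'   file are recorded as missing.
#' @return An `eldercohort`.
#' @export
read_panel <- function(path, mapping = NULL) {
  map <- default_panel_mapping()
  if (!is.null(mapping)) map[names(mapping)] <- mapping
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = c("NA", ""))
  need <- map[c("subject_id", "age", "state")]
  if (!all(need %in% names(raw))) {
    stop("panel file lacks required column(s): ",
         paste(setdiff(need, names(raw)), collapse = ", "))
  }
  df <- data.frame(id = as.character(raw[[map[["subject_id"]]]]),
                   age = as.numeric(raw[[map[["age"]]]]),
                   state = raw[[map[["state"]]]],
                   stringsAsFactors = FALSE)
  bad_state <- which(!(df$state %in% 0:2))
  if (length(bad_state) > 0) {
    stop("unknown state code ", df$state[bad_state[1]], " in row ",
         bad_state[1], " of ", path)
  }
  df$state <- as.integer(df$state)
  dcol <- map[["death_age"]]
  df$death_age <- if (dcol %in% names(raw)) as.numeric(raw[[dcol]]) else NA_real_
  for (v in covariate_columns()) {
    col <- map[[v]]
    df[[v]] <- if (col %in% names(raw)) as.character(raw[[col]]) else NA_character_
  }

  histories <- list()
  excluded <- list()
  for (id in unique(df$id)) {
    rows <- df[df$id == id, , drop = FALSE]
    ord <- order(rows$age)
    rows <- rows[ord, , drop = FALSE]
    death <- unique(rows$death_age[!is.na(rows$death_age)])
    if (length(death) > 1L) {
      stop("conflicting death ages for subject ", id)
    }
    death <- if (length(death) == 1L) death else NA_real_
    if (!is.na(death) && death <= max(rows$age)) {
      stop("death age ", death, " at or before last observation for subject ",
           id)
    }
    if (any(diff(rows$age) <= 0)) {
      excluded[[length(excluded) + 1L]] <-
        data.frame(id = id, reason = "non-monotone observation ages",
                   stringsAsFactors = FALSE)
      next
    }
    if ((nrow(rows) + sum(!is.na(death))) < 2L) {
      excluded[[length(excluded) + 1L]] <-
        data.frame(id = id, reason = "fewer than 2 information points",
                   stringsAsFactors = FALSE)
      next
    }
    covs <- as.list(rows[1, covariate_columns(), drop = FALSE])
    histories[[length(histories) + 1L]] <-
      subject_history(id, rows$age, rows$state, death, covs)
  }
  if (length(histories) == 0L) stop("no valid subjects in ", path)
  cohort <- make_cohort(histories)
  cohort$excluded <- if (length(excluded) > 0) {
    do.call(rbind, excluded)
  } else {
    data.frame(id = character(), reason = character(), stringsAsFactors = FALSE)
  }
  cohort
}

#' Write a cohort back to the long-format panel CSV
#'
#' Inverse of [read_panel()] on valid data: one row per observation with the
#' subject's death age and baseline covariates repeated on each row.
#'
#' @param cohort an `eldercohort`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(cohort, path) {
  obs <- cohort$observations
  subj <- cohort$subjects
  idx <- match(obs$id, subj$id)
  # 17 significant digits: ages survive the text round trip bit-exactly
  fmt <- function(x) ifelse(is.na(x), NA_character_, sprintf("%.17g", x))
  out <- data.frame(subject_id = obs$id, age = fmt(obs$age),
                    state = obs$state, death_age = fmt(subj$death_age[idx]),
                    stringsAsFactors = FALSE)
  for (v in covariate_columns()) out[[v]] <- subj[[v]][idx]
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}
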