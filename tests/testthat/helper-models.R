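# toy models and cohorts used across test files

# alive/dead survival submodel at a constant rate
surv_model <- function(rate) {
  intensity_model("survival", covariates = character(), age_form = "none",
                  log_baselines = log(rate))
}

# 4-state model with constant (age- and covariate-free) intensities
const_model4 <- function(rates) {
  m <- intensity_model("full", covariates = character(), age_form = "none")
  m$log_baselines[names(rates)] <- log(rates)
  m$log_baselines[setdiff(names(m$log_baselines), names(rates))] <- log(1e-8)
  m
}

# model with no allowed transitions at all (frozen chain, Q identically 0)
frozen_model <- function(nstates = 4L) {
  intensity_model(transitions = matrix(integer(), 0, 2), nstates = nstates,
                  covariates = character(), age_form = "none",
                  log_baselines = numeric())
}

# survival cohort: exponential death times at `rate`, censored at `cens`
surv_cohort <- function(n, rate, cens = 10, seed = 1) {
  set.seed(seed)
  t_death <- rexp(n, rate)
  histories <- lapply(seq_len(n), function(i) {
    if (t_death[i] < cens) {
      subject_history(i, 0, 0, death_age = t_death[i])
    } else {
      subject_history(i, c(0, cens), c(0, 0))
    }
  })
  make_cohort(histories)
}

# closed-form MLE for the survival cohort: deaths / person-time
surv_closed_form <- function(cohort) {
  d <- sum(!is.na(cohort$subjects$death_age))
  last_obs <- vapply(split(cohort$observations$age,
                           cohort$observations$id), max, 1)
  pt <- sum(ifelse(is.na(cohort$subjects$death_age),
                   last_obs[cohort$subjects$id],
                   cohort$subjects$death_age))
  d / pt
}

# build an eldercohort directly from count patterns (fast, no per-subject
# objects): `spec` rows give sex, region, entry state and a count
counts_cohort <- function(spec, entry_age = 65) {
  n <- sum(spec$count)
  idx <- rep(seq_len(nrow(spec)), spec$count)
  ids <- sprintf("c%05d", seq_len(n))
  subjects <- data.frame(id = ids, entry_age = entry_age,
                         death_age = NA_real_, stringsAsFactors = FALSE)
  for (v in covariate_columns()) subjects[[v]] <- NA_character_
  subjects$sex <- spec$sex[idx]
  subjects$region <- spec$region[idx]
  observations <- data.frame(
    id = rep(ids, each = 2),
    age = rep(c(entry_age, entry_age + 3), n),
    state = rep(spec$state[idx], each = 2), stringsAsFactors = FALSE)
  eldertrans:::new_cohort(subjects, observations)
}

# random constant 4-state intensity model (all 9 arrows)
random_model4 <- function(seed, lo = 0.02, hi = 0.4) {
  set.seed(seed)
  m <- intensity_model("full", covariates = character(), age_form = "none")
  m$log_baselines[] <- log(runif(9, lo, hi))
  m
}
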