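# Resolve a model covariate term to a numeric per-subject vector.
# "female"/"rural" derive from the sex/region columns; anything else must be
# a numeric column of the subjects table.
subject_covariate_values <- function(model, subjects) {
  C <- length(model$covariates)
  vals <- matrix(0, nrow(subjects), C,
                 dimnames = list(NULL, model$covariates))
  for (v in model$covariates) {
    x <- switch(v,
                female = as.numeric(subjects$sex == "female"),
                rural = as.numeric(subjects$region == "rural"),
                suppressWarnings(as.numeric(subjects[[v]])))
    if (length(x) != nrow(subjects) || anyNA(x)) {
      stop("covariate '", v, "' is missing or non-numeric for ",
           sum(is.na(x)), " subject(s); impute covariates before fitting")
    }
    vals[, v] <- x
  }
  vals
}

# Interval table for the panel likelihood. Each consecutive pair of living
# observations contributes one type-0 interval; an exactly dated death after
# the last living observation contributes one type-1 interval. Q is frozen
# at the interval midpoint age; the death-intensity factor is evaluated at
# the death age itself.
cohort_intervals <- function(cohort, model) {
  subj <- cohort$subjects
  obs <- cohort$observations
  sidx <- match(obs$id, subj$id)
  ord <- order(sidx, obs$age)
  obs <- obs[ord, , drop = FALSE]
  sidx <- sidx[ord]
  n <- nrow(obs)
  same <- sidx[-1] == sidx[-n]
  i1 <- which(same)

  liv <- data.frame(subj = sidx[i1], type = rep(0L, length(i1)),
                    from = obs$state[i1],
                    to = obs$state[i1 + 1L], dt = obs$age[i1 + 1L] - obs$age[i1],
                    anchor = (obs$age[i1] + obs$age[i1 + 1L]) / 2)
  liv$death_age <- liv$anchor

  last <- which(!duplicated(sidx, fromLast = TRUE))
  dsub <- sidx[last]
  has_death <- !is.na(subj$death_age[dsub])
  dl <- last[has_death]
  dth <- data.frame(subj = sidx[dl], type = rep(1L, length(dl)),
                    from = obs$state[dl], to = rep(-1L, length(dl)),
                    dt = subj$death_age[sidx[dl]] - obs$age[dl],
                    anchor = (subj$death_age[sidx[dl]] + obs$age[dl]) / 2,
                    death_age = subj$death_age[sidx[dl]])
  all_iv <- rbind(liv, dth)
  all_iv <- all_iv[order(all_iv$subj, all_iv$type, all_iv$anchor), , drop = FALSE]

  covvals <- subject_covariate_values(model, subj)
  build_Z <- function(age) {
    Z <- matrix(0, nrow(all_iv), length(model$design),
                dimnames = list(NULL, model$design))
    if (model$age_form == "loglinear") {
      Z[, "age"] <- age - model$age_center
    } else if (model$age_form == "bands") {
      Z[, "age_band2"] <- as.numeric(age >= model$age_breaks[1] &
                                       age < model$age_breaks[2])
      Z[, "age_band3"] <- as.numeric(age >= model$age_breaks[2])
    }
    if (length(model$covariates)) {
      Z[, model$covariates] <- covvals[all_iv$subj, model$covariates,
                                       drop = FALSE]
    }
    Z
  }
  list(
    ivl = cbind(subj = all_iv$subj - 1L, type = all_iv$type,
                from = all_iv$from, to = all_iv$to),
    dt = all_iv$dt,
    Z = build_Z(all_iv$anchor),
    Zd = build_Z(all_iv$death_age),
    n_subj = nrow(subj),
    ids = subj$id
  )
}

loglik_raw <- function(model, theta, iv, want_grad = FALSE) {
  storage.mode(iv$ivl) <- "integer"
  cohort_loglik_cpp(theta, model$transitions, model$nstates, iv$Z, iv$Zd,
                    iv$ivl, iv$dt, iv$n_subj, want_grad)
}

#' Cohort log-likelihood under an intensity model
#'
#' Sums each subject's interval-censored panel likelihood contribution.
#' Per-subject contributions are sorted by value before summation, so the
#' total is bit-identical under subject relabelling or reordering.
#'
#' @param model an [intensity_model()] with parameters set.
#' @param cohort an `eldercohort`.
#' @param want_grad if `TRUE`, attach the analytic score vector as
#'   attribute `"gradient"`.
#' @return The total log-likelihood; `-Inf` (with a diagnostic attribute
#'   `"impossible"`) if any subject's observed path has probability zero
#'   under the model's transition structure.
#' @export
cohort_loglik <- function(model, cohort, want_grad = FALSE) {
  iv <- cohort_intervals(cohort, model)
  res <- loglik_raw(model, model_theta(model), iv, want_grad)
  total <- sum(sort(res$ll_subj))
  if (!is.finite(total) && res$bad_row > 0) {
    attr(total, "impossible") <- sprintf(
      "structurally impossible transition %d->%d under the model structure",
      res$bad_from, res$bad_to)
  }
  if (want_grad) attr(total, "gradient") <- res$grad
  total
}

#' One subject's log-likelihood contribution
#'
#' Consecutive living observations (state r at age a1, state s at a2)
#' contribute \eqn{\log P_{rs}(a_1, a_2)} with Q frozen at the interval
#' midpoint age; an exactly dated death at age d after a last living
#' observation in state r at age a contributes
#' \eqn{\log \sum_{j} P_{rj}(a, d)\, q_{j,\mathrm{death}}(d)} over living
#' states j (exact death time, unknown state at death). Subjects lost after
#' their last interview contribute nothing beyond it (right censoring).
#'
#' @param model an [intensity_model()].
#' @param subject a [subject_history()].
#' @return Log-likelihood contribution; `-Inf` with a diagnostic attribute
#'   if the observed path is impossible under the transition structure.
#' @export
subject_loglik <- function(model, subject) {
  stopifnot(inherits(subject, "subject_history"))
  cohort_loglik(model, make_cohort(list(subject)))
}
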