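#' Empirical initial distribution of living states in a stratum
#'
#' Relative frequencies of the living states among baseline (first)
#' observations of subjects in a sex/region stratum whose entry age falls
#' within `index_age` plus/minus `window` years. Used to population-average
#' state-specific expectancies.
#'
#' @param cohort an `eldercohort`.
#' @param sex,region stratum filters (`NULL` = no restriction).
#' @param index_age centre of the age window in years.
#' @param window half-width of the age window in years (default 2.5).
#' @return Numeric vector of probabilities over states 0/1/2 (sums to 1).
#' @export
empirical_initial_distribution <- function(cohort, sex = NULL, region = NULL,
                                           index_age, window = 2.5) {
  subj <- cohort$subjects
  obs <- cohort$observations[order(cohort$observations$id,
                                   cohort$observations$age), ]
  first <- obs[!duplicated(obs$id), ]
  keep <- abs(first$age - index_age) <= window
  if (!is.null(sex)) {
    keep <- keep & !is.na(subj$sex[match(first$id, subj$id)]) &
      subj$sex[match(first$id, subj$id)] == sex
  }
  if (!is.null(region)) {
    keep <- keep & !is.na(subj$region[match(first$id, subj$id)]) &
      subj$region[match(first$id, subj$id)] == region
  }
  states <- first$state[keep]
  if (length(states) == 0L) {
    stop("no baseline observations within ", window, " years of age ",
         index_age, " in this stratum; widen `window`")
  }
  p <- tabulate(states + 1L, nbins = 3L) / length(states)
  stats::setNames(p, state_space()$labels[1:3])
}

#' Expected years in each state by initial state
#'
#' Multistate life-table estimator: \eqn{e_{rs} = \int_{a}^{A} P_{rs}(a, u)
#' \, du}, evaluated by the trapezoidal rule on an age grid with Q frozen at
#' subinterval midpoints. Total life expectancy from initial state r is the
#' row sum over living states.
#'
#' @param object an [intensity_model()] or [fit_mle()] result.
#' @param covariates named covariate profile (e.g.
#'   `list(female = 1, rural = 0)`).
#' @param index_age starting age a in years.
#' @param max_age integration cap A in years (default 115; survival beyond
#'   it is negligible for realistic intensities).
#' @param step grid step in years (default 0.25).
#' @param survival_warn warn when the living probability at `max_age`
#'   exceeds this threshold (expectancies are then visibly truncated).
#' @return List with `e` (living-by-living matrix of expected years), `tle`
#'   (total life expectancy per initial living state), and
#'   `survival_at_max`.
#' @export
state_expectancies <- function(object, covariates = list(), index_age,
                               max_age = 115, step = 0.25,
                               survival_warn = 0.01) {
  model <- as_intensity_model(object)
  stopifnot(step > 0, max_age > index_age)
  S <- model$nstates
  living <- seq_len(S - 1L)
  ages <- seq(index_age, max_age, by = step)
  if (ages[length(ages)] < max_age) ages <- c(ages, max_age)
  P <- diag(S)
  e <- matrix(0, S - 1L, S - 1L)
  prev_living <- P[living, living, drop = FALSE]
  for (i in seq_len(length(ages) - 1L)) {
    h <- ages[i + 1L] - ages[i]
    Q <- build_Q(model, covariates, age = (ages[i] + ages[i + 1L]) / 2)
    P <- P %*% expm_small(Q * h)
    cur_living <- P[living, living, drop = FALSE]
    e <- e + h * (prev_living + cur_living) / 2
    prev_living <- cur_living
  }
  surv <- rowSums(prev_living)
  if (any(surv > survival_warn)) {
    warning(sprintf(
      "survival probability at max_age = %g reaches %.3f; expectancies are truncated",
      max_age, max(surv)))
  }
  lab <- if (S == 4L) state_space()$labels[living] else paste0("state", living - 1L)
  dimnames(e) <- list(from = lab, instate = lab)
  list(e = e, tle = rowSums(e), survival_at_max = surv)
}

lt_quantity_names <- function() {
  c("TLE", "ND", "MD", "SD", "AD", "PND", "PMD", "PSD", "PAD")
}

lt_quantities <- function(years) {
  years <- unname(years)
  tle <- sum(years)
  props <- if (tle > 0) 100 * years / tle else rep(NA_real_, 3)
  c(TLE = tle, ND = years[1], MD = years[2], SD = years[3],
    AD = years[2] + years[3],
    PND = props[1], PMD = props[2], PSD = props[3],
    PAD = props[2] + props[3])
}

default_strata <- function(model) {
  if (all(c("female", "rural") %in% model$covariates)) {
    expand.grid(sex = c("male", "female"), region = c("urban", "rural"),
                stringsAsFactors = FALSE)
  } else {
    data.frame(sex = NA_character_, region = NA_character_,
               stringsAsFactors = FALSE)
  }
}

stratum_profile <- function(model, sex, region) {
  prof <- list()
  for (v in model$covariates) {
    prof[[v]] <- switch(v,
                        female = as.numeric(!is.na(sex) && sex == "female"),
                        rural = as.numeric(!is.na(region) && region == "rural"),
                        0)
  }
  prof
}

lifetable_points <- function(fit, cohort, strata, index_ages, max_age, step,
                             window) {
  model <- as_intensity_model(fit)
  init_labels <- c("population", state_space()$labels[1:3])
  out <- numeric()
  for (i in seq_len(nrow(strata))) {
    sex <- strata$sex[i]; region <- strata$region[i]
    prof <- stratum_profile(model, sex, region)
    for (a in index_ages) {
      ex <- state_expectancies(fit, prof, index_age = a, max_age = max_age,
                               step = step, survival_warn = 1.01)
      pi0 <- empirical_initial_distribution(
        cohort, sex = if (is.na(sex)) NULL else sex,
        region = if (is.na(region)) NULL else region,
        index_age = a, window = window)
      rows <- rbind(population = as.numeric(pi0 %*% ex$e), ex$e)
      for (r in seq_along(init_labels)) {
        q <- lt_quantities(rows[r, ])
        names(q) <- paste(sex, region, a, init_labels[r],
                          lt_quantity_names(), sep = "|")
        out <- c(out, q)
      }
    }
  }
  out
}

#' Multistate life table with health expectancies
#'
#' For each sex-by-region stratum and index age, computes total life
#' expectancy (TLE) and expected years with no (ND), mild (MD) and severe
#' (SD) disability, any-disability years (AD = MD + SD), and the
#' corresponding percentages of remaining life (PND, PMD, PSD, PAD), both
#' per initial living state and population-averaged over the stratum's
#' empirical initial distribution. Optional percentile-bootstrap confidence
#' intervals refit the model and recompute the whole pipeline on each
#' subject-level resample.
#'
#' @param fit an `msm_fit` (or bare [intensity_model()] for known-truth
#'   computations).
#' @param cohort the `eldercohort` supplying empirical initial
#'   distributions (and the bootstrap resampling frame).
#' @param index_ages index ages in years (default 65, 75, 85, 95).
#' @param strata data frame with columns `sex` and `region`; defaults to
#'   the four sex-by-region combinations when the model carries those
#'   covariates, else a single unstratified row.
#' @param max_age,step integration cap and grid step in years.
#' @param window half-width for the empirical initial distribution.
#' @param boot `NULL`, or a list with elements `B` and `seed` requesting
#'   bootstrap CIs (optionally `control` for the refits).
#' @return Tidy data frame: `sex`, `region`, `index_age`, `initial_state`,
#'   `quantity`, `estimate`, and `lo`/`hi` when bootstrapped.
#' @export
life_table <- function(fit, cohort, index_ages = c(65, 75, 85, 95),
                       strata = NULL, max_age = 115, step = 0.25,
                       window = 2.5, boot = NULL) {
  model <- as_intensity_model(fit)
  if (is.null(strata)) strata <- default_strata(model)
  pts <- lifetable_points(fit, cohort, strata, index_ages, max_age, step,
                          window)
  lo <- hi <- rep(NA_real_, length(pts))
  if (!is.null(boot)) {
    ctl <- if (is.null(boot$control)) list(hessian = FALSE) else boot$control
    bs <- bootstrap_ci(
      cohort, model,
      statistic = function(f, ch) lifetable_points(f, ch, strata, index_ages,
                                                   max_age, step, window),
      B = if (is.null(boot$B)) 499L else boot$B,
      seed = if (is.null(boot$seed)) 1L else boot$seed,
      init = if (inherits(fit, "msm_fit")) fit$theta else NULL,
      control = ctl)
    lo <- bs$ci["lo", ]
    hi <- bs$ci["hi", ]
  }
  parts <- strsplit(names(pts), "|", fixed = TRUE)
  out <- data.frame(
    sex = vapply(parts, `[`, "", 1L),
    region = vapply(parts, `[`, "", 2L),
    index_age = as.numeric(vapply(parts, `[`, "", 3L)),
    initial_state = vapply(parts, `[`, "", 4L),
    quantity = vapply(parts, `[`, "", 5L),
    estimate = unname(pts), lo = unname(lo), hi = unname(hi),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Render a life table in the conventional wide layout
#'
#' @param lt output of [life_table()].
#' @param initial_state which initial-state block to print.
#' @return Character lines, invisibly; also printed. Years are shown with
#'   two decimals, proportions with one (display only).
#' @export
format_life_table <- function(lt, initial_state = "population") {
  t <- lt[lt$initial_state == initial_state, ]
  lines <- character()
  for (a in unique(t$index_age)) {
    lines <- c(lines, sprintf("-- index age %g (initial state: %s) --", a,
                              initial_state))
    ta <- t[t$index_age == a, ]
    strata <- unique(ta[, c("sex", "region")])
    for (q in lt_quantity_names()) {
      vals <- vapply(seq_len(nrow(strata)), function(i) {
        v <- ta$estimate[ta$sex %in% strata$sex[i] &
                           ta$region %in% strata$region[i] & ta$quantity == q]
        if (substr(q, 1, 1) == "P") sprintf("%6.1f", round_half_up(v, 1))
        else sprintf("%6.2f", round_half_up(v, 2))
      }, "")
      lines <- c(lines, sprintf("  %-4s %s", q, paste(vals, collapse = "  ")))
    }
  }
  cat(lines, sep = "\n")
  invisible(lines)
}
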