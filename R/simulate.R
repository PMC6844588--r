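#' Default ground-truth intensity model for synthetic cohorts
#'
#' A full-structure model with log-linear age effects and female/rural
#' covariate effects, chosen to echo the qualitative phenomena of elderly
#' disability dynamics at realistic magnitudes: disability incidence and
#' mortality rising steeply with age, recovery declining with age, female
#' excess disability incidence, male excess mortality, and a rural recovery
#' advantage. Baselines are rates per person-year for an urban man aged 65.
#'
#' @return An [intensity_model()] with parameters set.
#' @export
default_true_model <- function() {
  m <- intensity_model("full", covariates = c("female", "rural"),
                       age_form = "loglinear", age_center = 65)
  tn <- names(m$log_baselines)
  base <- c(q01 = 0.050, q02 = 0.010, q03 = 0.020,
            q10 = 0.250, q12 = 0.060, q13 = 0.040,
            q20 = 0.080, q21 = 0.150, q23 = 0.150)
  age <- c(q01 = 0.07, q02 = 0.08, q03 = 0.09,
           q10 = -0.05, q12 = 0.07, q13 = 0.08,
           q20 = -0.06, q21 = -0.04, q23 = 0.07)
  female <- c(q01 = 0.25, q02 = 0.15, q03 = -0.35,
              q10 = -0.10, q12 = 0.15, q13 = -0.30,
              q20 = -0.10, q21 = -0.05, q23 = -0.25)
  rural <- c(q01 = 0.15, q02 = 0.00, q03 = 0.10,
             q10 = 0.20, q12 = -0.15, q13 = 0.10,
             q20 = 0.15, q21 = 0.20, q23 = 0.10)
  m$log_baselines[] <- log(base[tn])
  m$betas[, "age"] <- age[tn]
  m$betas[, "female"] <- female[tn]
  m$betas[, "rural"] <- rural[tn]
  m
}

default_entry_state_probs <- function() {
  p <- rbind("male|urban" = c(55.9, 27.7, 16.4),
             "female|urban" = c(40.2, 37.4, 22.5),
             "male|rural" = c(54.0, 34.8, 11.2),
             "female|rural" = c(37.7, 45.1, 17.3))
  sweep(p, 1, rowSums(p), "/")
}

# baseline covariate frequencies by stratum (male|urban, female|urban,
# male|rural, female|rural), echoing typical elderly-survey magnitudes
default_covariate_freqs <- function() {
  list(
    education = rbind(c(0.267, 0.473, 0.260), c(0.698, 0.215, 0.087),
                      c(0.406, 0.475, 0.119), c(0.854, 0.134, 0.012)),
    marital = c(0.558, 0.241, 0.500, 0.251),
    smoking = c(0.329, 0.083, 0.401, 0.070),
    drinking = c(0.305, 0.091, 0.358, 0.100),
    exercise = c(0.529, 0.381, 0.273, 0.188),
    expenses = c(0.852, 0.796, 0.774, 0.756),
    medical = c(0.944, 0.921, 0.895, 0.878),
    diabetes = c(0.041, 0.040, 0.012, 0.017),
    heart_disease = c(0.119, 0.143, 0.052, 0.066),
    stroke = c(0.081, 0.064, 0.050, 0.044)
  )
}

#' Default per-covariate item-missingness rates
#'
#' Small per-item deletion probabilities of the order seen in large elderly
#' surveys (a fraction of a percent), named by covariate.
#'
#' @return Named numeric vector of rates.
#' @export
default_missing_rates <- function() {
  c(education = 0.0037, marital = 0.0001, smoking = 0.0007,
    drinking = 0.0007, expenses = 0.0002, medical = 0.0002,
    exercise = 0.0015, diabetes = 0.0003, heart_disease = 0.0002,
    stroke = 0.00025)
}

#' Parameter-recovery calibration scenario
#'
#' A well-posed estimator-validation design: every transition arrow of the
#' no-jump structure carries a rate (0.06-0.15 per person-year) chosen so
#' that five triennial waves yield adequate expected event counts on each
#' arrow, the age covariate is centred at 71 (the person-time centre of the
#' follow-up window, which keeps baseline estimates in the data-dense
#' region), entry is young (ages 65-68) with entry states (0.4, 0.3, 0.3),
#' covariates are balanced (P(female) = P(rural) = 0.5), and there is no
#' dropout. See the methods vignette for the design rationale.
#'
#' @param n subjects (default 2000).
#' @param seed integer seed.
#' @return A [simulation_scenario()].
#' @export
calibration_scenario <- function(n = 2000L, seed = 1L) {
  m <- intensity_model("no-jump", covariates = c("female", "rural"),
                       age_form = "loglinear", age_center = 71)
  tn <- names(m$log_baselines)
  base <- c(q01 = 0.12, q03 = 0.06, q10 = 0.15, q12 = 0.09, q13 = 0.075,
            q21 = 0.14, q23 = 0.10)
  age <- c(q01 = 0.04, q03 = 0.05, q10 = -0.03, q12 = 0.04, q13 = 0.05,
           q21 = -0.03, q23 = 0.05)
  female <- c(q01 = 0.25, q03 = -0.30, q10 = -0.10, q12 = 0.15,
              q13 = -0.25, q21 = -0.10, q23 = -0.20)
  rural <- c(q01 = 0.15, q03 = 0.10, q10 = 0.20, q12 = -0.15, q13 = 0.10,
             q21 = 0.20, q23 = 0.10)
  m$log_baselines[] <- log(base[tn])
  m$betas[, "age"] <- age[tn]
  m$betas[, "female"] <- female[tn]
  m$betas[, "rural"] <- rural[tn]
  probs <- matrix(rep(c(0.4, 0.3, 0.3), each = 4), 4,
                  dimnames = list(c("male|urban", "female|urban",
                                    "male|rural", "female|rural"), NULL))
  simulation_scenario(n = n, model = m, entry_age_range = c(65, 68),
                      p_female = 0.5, p_rural = 0.5,
                      entry_state_probs = probs, dropout = 0,
                      seed = seed)
}

#' Synthetic panel-survey scenario
#'
#' Collects the ground-truth intensity model and the survey-design
#' parameters used by [generate_cohort()]: staggered entry ages on
#' [65, 95], interview waves at three-year spacing (entry + 0, 3, 6, 9, 12
#' years), per-wave dropout, exactly dated deaths between attended waves,
#' stratum-specific entry-state and covariate frequencies, and item-level
#' covariate missingness.
#'
#' @param n number of subjects.
#' @param model ground-truth [intensity_model()].
#' @param entry_age_range range of uniform entry ages in years.
#' @param p_female,p_rural marginal probabilities of female sex and rural
#'   residence.
#' @param entry_state_probs 4 x 3 matrix of entry-state probabilities by
#'   stratum (rows `male|urban`, `female|urban`, `male|rural`,
#'   `female|rural`).
#' @param waves interview offsets from entry, in years, increasing.
#' @param dropout per-wave probability of permanent loss to follow-up
#'   (applies to each wave after the first).
#' @param missing_rates named per-covariate missingness rates.
#' @param covariate_freqs stratum-specific categorical frequencies.
#' @param micro age-freezing micro-step for the trajectory simulator.
#' @param seed integer seed.
#' @return An object of class `simulation_scenario`.
#' @export
simulation_scenario <- function(n = 2000L, model = default_true_model(),
                                entry_age_range = c(65, 95),
                                p_female = 0.5, p_rural = 0.605,
                                entry_state_probs = default_entry_state_probs(),
                                waves = c(0, 3, 6, 9, 12),
                                dropout = 0.08,
                                missing_rates = default_missing_rates(),
                                covariate_freqs = default_covariate_freqs(),
                                micro = 0.1, seed = 1L) {
  stopifnot(n >= 1L, all(diff(waves) > 0),
            all(c(p_female, p_rural, dropout) >= 0),
            all(c(p_female, p_rural, dropout) <= 1))
  structure(list(n = as.integer(n), model = model,
                 entry_age_range = entry_age_range, p_female = p_female,
                 p_rural = p_rural, entry_state_probs = entry_state_probs,
                 waves = waves, dropout = dropout,
                 missing_rates = missing_rates,
                 covariate_freqs = covariate_freqs, micro = micro,
                 seed = as.integer(seed)),
            class = "simulation_scenario")
}

sim_model_args <- function(model, covariates) {
  z <- numeric(length(model$design))
  names(z) <- model$design
  for (v in model$covariates) {
    val <- covariates[[v]]
    if (is.null(val) || is.na(val)) stop("covariate '", v, "' missing")
    z[v] <- as.numeric(val)
  }
  form <- switch(model$age_form, none = 0L, loglinear = 1L, bands = 2L)
  cols <- match(age_design_cols(model$age_form), model$design) - 1L
  pars <- switch(model$age_form, none = 0, loglinear = model$age_center,
                 bands = model$age_breaks)
  list(theta = model_theta(model), trans = model$transitions,
       S = model$nstates, z = z, form = form,
       cols = as.integer(if (length(cols)) cols else 0L),
       pars = as.numeric(pars))
}

#' Simulate one continuous-time disability trajectory
#'
#' Gillespie-style forward simulation of the continuous-time Markov
#' process: exponential holding times at rates frozen over `micro`-year
#' steps to honour age dependence, next state drawn proportionally to the
#' transition intensities, stopping at death or at `entry_age + horizon`.
#'
#' @param model an [intensity_model()].
#' @param covariates named covariate values for the model's terms.
#' @param entry_age entry age in years.
#' @param entry_state initial living state (0/1/2).
#' @param horizon follow-up horizon in years (must be finite).
#' @param micro age-freezing step in years (default 0.1).
#' @return Data frame `(age, state)`: entry row, one row per state change,
#'   final row at death or at the horizon.
#' @export
simulate_trajectory <- function(model, covariates = list(), entry_age,
                                entry_state = 0L, horizon, micro = 0.1) {
  if (missing(horizon) || !is.finite(horizon)) {
    stop("a finite horizon is required (intensities may be zero)")
  }
  stopifnot(entry_state %in% 0:(model$nstates - 2L))
  a <- sim_model_args(model, covariates)
  path <- sim_path_cpp(a$theta, a$trans, a$S, a$z, a$form, a$cols, a$pars,
                       entry_age, as.integer(entry_state), horizon, micro)
  data.frame(age = path[, 1], state = as.integer(path[, 2]))
}

state_at_age <- function(trajectory, age) {
  idx <- max(which(trajectory$age <= age + 1e-12))
  trajectory$state[idx]
}

#' Sample a trajectory at the survey waves
#'
#' Applies the wave design to a continuous trajectory: the state is
#' recorded at each attended wave while alive; dropout at a follow-up wave
#' ends all further contact; a death is dated exactly only when a later
#' attended contact exists to report it. Subjects left with fewer than two
#' information points are flagged for exclusion, mirroring the exclusion of
#' pre-first-follow-up dropouts.
#'
#' @param trajectory data frame from [simulate_trajectory()].
#' @param wave_ages interview ages in years.
#' @param dropout per-wave dropout probability (waves after the first).
#' @param death_state state code of the absorbing death state.
#' @return List with `obs_ages`, `obs_states`, `death_age` (NA when not
#'   ascertained) and the `excluded` flag.
#' @export
sample_waves <- function(trajectory, wave_ages, dropout = 0,
                         death_state = 3L) {
  last <- nrow(trajectory)
  death_age <- if (trajectory$state[last] == death_state)
    trajectory$age[last] else NA_real_
  attended <- wave_ages[1]
  for (w in wave_ages[-1]) {
    if (stats::runif(1) < dropout) break
    attended <- c(attended, w)
  }
  alive_at <- function(a) is.na(death_age) || a < death_age
  obs_ages <- attended[vapply(attended, alive_at, TRUE)]
  obs_states <- vapply(obs_ages, function(a) state_at_age(trajectory, a), 0L)
  death_seen <- !is.na(death_age) && any(attended >= death_age)
  rec_death <- if (death_seen) death_age else NA_real_
  excluded <- (length(obs_ages) + !is.na(rec_death)) < 2L
  list(obs_ages = obs_ages, obs_states = obs_states, death_age = rec_death,
       excluded = excluded)
}

draw_covariates <- function(scenario) {
  n <- scenario$n
  sex <- ifelse(stats::runif(n) < scenario$p_female, "female", "male")
  region <- ifelse(stats::runif(n) < scenario$p_rural, "rural", "urban")
  stratum <- match(paste(sex, region, sep = "|"),
                   c("male|urban", "female|urban", "male|rural",
                     "female|rural"))
  lev <- covariate_levels()
  fq <- scenario$covariate_freqs
  covs <- data.frame(sex = sex, region = region, stringsAsFactors = FALSE)
  covs$marital <- ifelse(stats::runif(n) < fq$marital[stratum],
                         "married", "others")
  edu_p <- fq$education[stratum, , drop = FALSE]
  u <- stats::runif(n)
  covs$education <- ifelse(u < edu_p[, 1], "0y",
                           ifelse(u < edu_p[, 1] + edu_p[, 2], "1-6y", "7+y"))
  for (v in c("smoking", "drinking", "exercise", "diabetes",
              "heart_disease", "stroke")) {
    covs[[v]] <- ifelse(stats::runif(n) < fq[[v]][stratum],
                        lev[[v]][2], lev[[v]][1])
  }
  covs$expenses <- ifelse(stats::runif(n) < fq$expenses[stratum],
                          "sufficient", "insufficient")
  covs$medical <- ifelse(stats::runif(n) < fq$medical[stratum],
                         "adequate", "inadequate")
  covs
}

#' Generate a synthetic panel cohort with known ground truth
#'
#' Draws covariates and entry states, simulates continuous-time
#' trajectories under the scenario's true intensity model, samples them at
#' the wave schedule with dropout and exact death dating, injects
#' item-level covariate missingness, and assembles a validated cohort plus
#' a ground-truth record (true parameters, scenario settings, seed, and —
#' when `truth_sim_n > 0` — true life-table quantities per stratum computed
#' by trajectory averaging).
#'
#' @param scenario a [simulation_scenario()].
#' @param truth_sim_n trajectories per stratum for the truth life-table
#'   sidecar (0 to skip).
#' @param truth_horizon horizon in years for truth occupancy averaging.
#' @return List with `cohort` (an `eldercohort`; flagged-for-exclusion
#'   subjects appear in its `excluded` table) and `truth`.
#' @export
generate_cohort <- function(scenario, truth_sim_n = 0L, truth_horizon = 50) {
  set.seed(scenario$seed)
  n <- scenario$n
  covs <- draw_covariates(scenario)
  entry_age <- stats::runif(n, scenario$entry_age_range[1],
                            scenario$entry_age_range[2])
  stratum <- match(paste(covs$sex, covs$region, sep = "|"),
                   rownames(scenario$entry_state_probs))
  entry_state <- vapply(seq_len(n), function(i) {
    sample(0:2, 1, prob = scenario$entry_state_probs[stratum[i], ])
  }, 0L)
  horizon <- max(scenario$waves)
  histories <- list()
  excluded <- list()
  miss <- scenario$missing_rates
  for (i in seq_len(n)) {
    prof <- list(female = as.numeric(covs$sex[i] == "female"),
                 rural = as.numeric(covs$region[i] == "rural"))
    traj <- simulate_trajectory(scenario$model, prof, entry_age[i],
                                entry_state[i], horizon = horizon + 1e-9,
                                micro = scenario$micro)
    sw <- sample_waves(traj, entry_age[i] + scenario$waves, scenario$dropout)
    cv <- as.list(covs[i, , drop = FALSE])
    for (v in names(miss)) {
      if (stats::runif(1) < miss[[v]]) cv[[v]] <- NA_character_
    }
    id <- sprintf("s%05d", i)
    if (sw$excluded) {
      excluded[[length(excluded) + 1L]] <- data.frame(
        id = id, reason = "dropped out before first follow-up",
        stringsAsFactors = FALSE)
      next
    }
    histories[[length(histories) + 1L]] <-
      subject_history(id, sw$obs_ages, sw$obs_states, sw$death_age, cv)
  }
  cohort <- make_cohort(histories)
  if (length(excluded)) cohort$excluded <- do.call(rbind, excluded)
  truth <- list(theta = as.list(stats::setNames(model_theta(scenario$model),
                                                theta_names(scenario$model))),
                structure = scenario$model$structure,
                age_form = scenario$model$age_form,
                seed = scenario$seed, n = n,
                waves = scenario$waves, dropout = scenario$dropout,
                n_excluded = length(excluded))
  if (truth_sim_n > 0L) {
    truth$lifetable <- truth_lifetable(scenario$model, truth_sim_n,
                                       truth_horizon,
                                       micro = scenario$micro)
  }
  list(cohort = cohort, truth = truth)
}

#' True state occupancy by trajectory averaging
#'
#' Monte-Carlo reference for the life-table estimator: mean years spent in
#' each living state over `[age, age + horizon]` among `n` simulated
#' trajectories from a given initial state and profile.
#'
#' @param model an [intensity_model()].
#' @param covariates named covariate profile.
#' @param age starting age; `state` starting living state.
#' @param horizon years simulated; `n` number of trajectories.
#' @param micro age-freezing step; `record_t` optional offset at which the
#'   occupied state is recorded (for one-year frequency checks).
#' @return List with `mean_occupancy` (years per state), `tle`, the
#'   `state_at` tabulation at `record_t`, and mean observed lifetime.
#' @export
simulate_occupancy <- function(model, covariates = list(), age, state = 0L,
                               horizon = 50, n = 10000L, micro = 0.1,
                               record_t = 1) {
  a <- sim_model_args(model, covariates)
  res <- sim_batch_cpp(as.integer(n), a$theta, a$trans, a$S, a$z, a$form,
                       a$cols, a$pars, age, as.integer(state), horizon,
                       micro, record_t)
  occ <- res$occupancy
  living <- seq_len(a$S - 1L)
  list(mean_occupancy = colMeans(occ)[living],
       tle = mean(rowSums(occ[, living, drop = FALSE])),
       state_at = tabulate(res$state_at + 1L, nbins = a$S) / n,
       mean_lifetime = mean(rowSums(occ[, living, drop = FALSE])),
       death_age = res$death_age)
}

truth_lifetable <- function(model, n_sim, horizon, micro = 0.1) {
  out <- list()
  for (sex in c("male", "female")) {
    for (region in c("urban", "rural")) {
      prof <- list(female = as.numeric(sex == "female"),
                   rural = as.numeric(region == "rural"))
      occ <- simulate_occupancy(model, prof, age = 65, state = 0L,
                                horizon = horizon, n = n_sim, micro = micro)
      out[[paste(sex, region, sep = "|")]] <- list(
        index_age = 65, initial_state = "no_disability",
        TLE = occ$tle, ND = occ$mean_occupancy[1],
        MD = occ$mean_occupancy[2], SD = occ$mean_occupancy[3])
    }
  }
  out
}

#' Write the ground-truth sidecar JSON
#'
#' @param truth the `truth` element of [generate_cohort()]'s result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
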