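default_transitions <- function(structure, nstates) {
  living <- seq_len(nstates - 1L) - 1L
  death <- nstates - 1L
  if (structure == "survival") {
    return(matrix(c(0L, 1L), ncol = 2))
  }
  pairs <- expand.grid(from = living, to = living)
  pairs <- pairs[pairs$from != pairs$to, ]
  if (structure == "no-jump") {
    pairs <- pairs[abs(pairs$from - pairs$to) == 1L, ]
  }
  tr <- rbind(as.matrix(pairs), cbind(from = living, to = death))
  tr <- tr[order(tr[, 1], tr[, 2]), , drop = FALSE]
  storage.mode(tr) <- "integer"
  unname(tr)
}

age_design_cols <- function(age_form) {
  switch(age_form,
         loglinear = "age",
         bands = c("age_band2", "age_band3"),
         none = character())
}

#' Continuous-time Markov intensity model with covariate effects
#'
#' Defines the allowed transition structure and the log-linear intensity
#' regression \eqn{q_{rs}(z) = \exp(\log b_{rs} + \beta_{rs} \cdot z)}.
#' The reference covariate profile is an urban male aged `age_center`
#' (default 65), which fixes the meaning of the baselines. Age may enter
#' log-linearly (continuous, centred at `age_center`) or as band indicators
#' (default bands 75-84 and 85+, mirroring the usual 65-74/75-84/85+
#' grouping), or not at all.
#'
#' @param structure `"full"` (all 6 transitions among living states plus the
#'   3 living-to-death arrows), `"no-jump"` (direct no-disability to/from
#'   severe jumps forbidden), or `"survival"` (two states alive/dead, for
#'   survival-only submodels).
#' @param covariates character vector of covariate effect names; `"female"`
#'   and `"rural"` are resolved from the cohort's sex/region columns, other
#'   names must be numeric columns of the subjects table.
#' @param age_form `"loglinear"`, `"bands"` or `"none"`.
#' @param age_center centring age in years for the log-linear form.
#' @param age_breaks two ages delimiting the upper bands for `"bands"`.
#' @param log_baselines numeric vector of log intensities per allowed
#'   transition (per person-year at the reference profile); defaults to
#'   `log(0.1)`.
#' @param betas matrix (transitions x design columns) of log-scale covariate
#'   effects; defaults to zeros.
#' @param nstates number of states (death is always the last state).
#' @param transitions optional explicit 2-column matrix of allowed
#'   transitions (0-based state codes), overriding `structure`.
#' @return An object of class `intensity_model`.
#' @export
intensity_model <- function(structure = c("full", "no-jump", "survival"),
                            covariates = c("female", "rural"),
                            age_form = c("loglinear", "bands", "none"),
                            age_center = 65, age_breaks = c(75, 85),
                            log_baselines = NULL, betas = NULL, nstates = 4L,
                            transitions = NULL) {
  structure <- match.arg(structure)
  age_form <- match.arg(age_form)
  if (structure == "survival") nstates <- 2L
  if (is.null(transitions)) transitions <- default_transitions(structure, nstates)
  storage.mode(transitions) <- "integer"
  if (any(transitions[, 1] == nstates - 1L)) {
    stop("the death state cannot have outgoing transitions")
  }
  K <- nrow(transitions)
  design <- c(age_design_cols(age_form), covariates)
  C <- length(design)
  if (is.null(log_baselines)) log_baselines <- rep(log(0.1), K)
  if (length(log_baselines) != K) stop("need one log baseline per transition")
  if (!all(is.finite(log_baselines))) stop("log baselines must be finite")
  if (is.null(betas)) betas <- matrix(0, K, C)
  betas <- matrix(as.numeric(betas), K, C)
  tn <- if (K == 0L) character() else
    paste0("q", transitions[, 1], transitions[, 2])
  names(log_baselines) <- tn
  dimnames(betas) <- list(tn, design)
  structure(
    list(structure = structure, nstates = as.integer(nstates),
         transitions = transitions, covariates = covariates,
         age_form = age_form, age_center = age_center,
         age_breaks = age_breaks, design = design,
         log_baselines = stats::setNames(as.numeric(log_baselines), tn),
         betas = betas),
    class = "intensity_model"
  )
}

#' @export
print.intensity_model <- function(x, ...) {
  cat("Intensity model:", x$structure, "structure,", x$nstates, "states\n")
  cat("  transitions:",
      paste(paste0(x$transitions[, 1], "->", x$transitions[, 2]),
            collapse = " "), "\n")
  cat("  age form:", x$age_form, "| covariates:",
      if (length(x$covariates)) paste(x$covariates, collapse = ", ")
      else "(none)", "\n")
  cat("  baseline intensities (reference profile):\n")
  print(round(exp(x$log_baselines), 5))
  invisible(x)
}

model_theta <- function(model) {
  c(model$log_baselines, as.numeric(t(model$betas)))
}

theta_names <- function(model) {
  tn <- names(model$log_baselines)
  if (length(model$design) == 0) return(tn)
  c(tn, as.vector(t(outer(tn, model$design, paste, sep = ":"))))
}

set_theta <- function(model, theta) {
  K <- nrow(model$transitions)
  C <- length(model$design)
  model$log_baselines[] <- theta[seq_len(K)]
  if (C > 0) model$betas[] <- matrix(theta[-seq_len(K)], K, C, byrow = TRUE)
  model
}

# numeric design row at a covariate profile and age; `covariates` is a named
# list/vector with entries for the model's covariate terms (female, rural, ...)
design_row_r <- function(model, covariates, age) {
  z <- numeric(length(model$design))
  names(z) <- model$design
  if (model$age_form == "loglinear") {
    z["age"] <- age - model$age_center
  } else if (model$age_form == "bands") {
    z["age_band2"] <- as.numeric(age >= model$age_breaks[1] &
                                   age < model$age_breaks[2])
    z["age_band3"] <- as.numeric(age >= model$age_breaks[2])
  }
  for (v in model$covariates) {
    val <- covariates[[v]]
    if (is.null(val) || is.na(val)) {
      stop("covariate '", v, "' is missing for this profile; ",
           "impute covariates before building intensities")
    }
    z[v] <- as.numeric(val)
  }
  z
}

#' Build the transition intensity matrix at a covariate profile
#'
#' Evaluates \eqn{Q(z, \mathrm{age})}: off-diagonal entries
#' \eqn{q_{rs} = \exp(\log b_{rs} + \beta_{rs} \cdot z)} for allowed
#' transitions, zero otherwise, diagonal set to minus the row sum. Rows sum
#' to zero and the death row is identically zero.
#'
#' @param model an [intensity_model()].
#' @param covariates named list of covariate values for the model's terms,
#'   e.g. `list(female = 1, rural = 0)`.
#' @param age age in years.
#' @return An `nstates x nstates` intensity matrix (per person-year).
#' @export
build_Q <- function(model, covariates = list(), age = model$age_center) {
  stopifnot(is.finite(age))
  z <- design_row_r(model, covariates, age)
  K <- nrow(model$transitions)
  q <- exp(model$log_baselines +
             if (length(z)) as.numeric(model$betas %*% z) else 0)
  S <- model$nstates
  Q <- matrix(0, S, S)
  for (k in seq_len(K)) {
    f <- model$transitions[k, 1] + 1L
    t <- model$transitions[k, 2] + 1L
    Q[f, t] <- Q[f, t] + q[k]
    Q[f, f] <- Q[f, f] - q[k]
  }
  lab <- if (S == 4L) state_space()$labels else paste0("state", 0:(S - 1))
  dimnames(Q) <- list(lab, lab)
  Q
}
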