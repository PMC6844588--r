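expm_small <- function(M) {
  as.matrix(Matrix::expm(Matrix::Matrix(M)))
}

#' Transition probability matrix over an age interval
#'
#' Computes \eqn{P(a_1, a_2)} for a covariate profile under the age-varying
#' intensity model, as the product of matrix exponentials
#' \eqn{\prod \exp(Q(a) h)} over subintervals of width at most `step`, with
#' \eqn{Q} frozen at each subinterval's midpoint age. Returns the identity
#' when `a1 == a2`.
#'
#' @param model an [intensity_model()] or fitted model ([fit_mle()]).
#' @param covariates named list of covariate values (e.g.
#'   `list(female = 0, rural = 0)`).
#' @param a1,a2 interval endpoints in years, `a1 <= a2`.
#' @param step maximal subinterval width in years (default 0.5).
#' @return A row-stochastic `nstates x nstates` probability matrix.
#' @export
transition_probability <- function(model, covariates = list(), a1, a2,
                                   step = 0.5) {
  model <- as_intensity_model(model)
  stopifnot(a1 <= a2, step > 0)
  S <- model$nstates
  lab <- if (S == 4L) state_space()$labels else paste0("state", 0:(S - 1))
  P <- diag(S)
  dimnames(P) <- list(lab, lab)
  if (a2 == a1) return(P)
  n_pieces <- max(1L, ceiling((a2 - a1) / step - 1e-12))
  breaks <- seq(a1, a2, length.out = n_pieces + 1L)
  for (i in seq_len(n_pieces)) {
    h <- breaks[i + 1L] - breaks[i]
    Q <- build_Q(model, covariates, age = (breaks[i] + breaks[i + 1L]) / 2)
    P <- P %*% expm_small(Q * h)
  }
  P[P < 0 & P > -1e-12] <- 0
  rs <- rowSums(P)
  if (any(abs(rs - 1) > 1e-8) || any(P < 0) || any(P > 1 + 1e-8)) {
    stop("internal consistency error: transition matrix is not stochastic ",
         "(max row-sum deviation ", format(max(abs(rs - 1))), ")")
  }
  dimnames(P) <- list(lab, lab)
  P
}

as_intensity_model <- function(object) {
  if (inherits(object, "intensity_model")) return(object)
  if (inherits(object, "msm_fit")) return(object$model)
  stop("expected an intensity_model or msm_fit object")
}

#' Annual transition probability matrix at a given age
#'
#' \eqn{P(\mathrm{age}, \mathrm{age}+1)} for a sex/region profile under the
#' (fitted) age-varying model; the machinery behind annual transition
#' probability curves over ages 65-95.
#'
#' @param object an [intensity_model()] or [fit_mle()] result.
#' @param covariates named list of covariate values.
#' @param age age in years at the start of the one-year interval.
#' @param step grid step passed to [transition_probability()].
#' @param max_age ages beyond `max_age - 1` are capped with a warning
#'   rather than extrapolated.
#' @return A row-stochastic probability matrix.
#' @export
annual_probability <- function(object, covariates = list(), age, step = 0.5,
                               max_age = 110) {
  if (age > max_age - 1) {
    warning("age ", age, " beyond supported range; capped at ", max_age - 1)
    age <- max_age - 1
  }
  transition_probability(object, covariates, age, age + 1, step = step)
}

#' Annual transition probability curves by age
#'
#' Tabulates every allowed transition's annual probability over a span of
#' ages for one covariate profile, in long format suitable for plotting or
#' CSV export.
#'
#' @param object an [intensity_model()] or [fit_mle()] result.
#' @param covariates named list of covariate values.
#' @param ages vector of ages (default 65 to 95).
#' @param step grid step in years.
#' @return Data frame with columns `age`, `from`, `to`, `probability`.
#' @export
annual_probability_curves <- function(object, covariates = list(),
                                      ages = 65:95, step = 0.5) {
  model <- as_intensity_model(object)
  out <- list()
  for (a in ages) {
    P <- annual_probability(object, covariates, a, step = step)
    for (k in seq_len(nrow(model$transitions))) {
      f <- model$transitions[k, 1]
      t <- model$transitions[k, 2]
      out[[length(out) + 1L]] <- data.frame(
        age = a, from = f, to = t, probability = P[f + 1L, t + 1L])
    }
  }
  do.call(rbind, out)
}
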