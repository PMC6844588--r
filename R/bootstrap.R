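resample_cohort <- function(cohort, idx) {
  subj <- cohort$subjects[idx, , drop = FALSE]
  new_ids <- sprintf("bs%06d", seq_along(idx))
  obs_split <- split(seq_len(nrow(cohort$observations)),
                     match(cohort$observations$id, cohort$subjects$id))
  rows <- obs_split[as.character(idx)]
  obs <- cohort$observations[unlist(rows, use.names = FALSE), , drop = FALSE]
  obs$id <- rep(new_ids, vapply(rows, length, 1L))
  subj$id <- new_ids
  new_cohort(subj, obs)
}

#' Nonparametric bootstrap confidence intervals for model functionals
#'
#' Resamples subjects (not rows) with replacement, refits the intensity
#' model on each resample, evaluates a statistic of the fitted model, and
#' returns percentile 95% intervals per statistic component. The default
#' B = 499 resamples follows the usual odd-B percentile convention.
#' Randomness is driven by a single seed expanded into per-replicate
#' substreams, which are recorded in the result.
#'
#' @param cohort an `eldercohort`.
#' @param model an [intensity_model()].
#' @param statistic function of the fitted `msm_fit` (and optionally the
#'   resampled cohort: `function(fit, cohort)`) returning a numeric vector.
#' @param B number of bootstrap resamples (default 499).
#' @param seed integer seed.
#' @param init optional starting values for the refits (defaults to the
#'   full-data fit's estimates, which speeds convergence).
#' @param control optimizer control passed to [fit_mle()].
#' @return List with the percentile `ci` matrix (rows `lo`/`hi`), the
#'   replicate value matrix, `B`, `seed`, the per-replicate `substreams`,
#'   the count of failed replicates and their rate, and `unreliable = TRUE`
#'   when more than 20% of replicates failed.
#' @export
bootstrap_ci <- function(cohort, model, statistic, B = 499L, seed = 1L,
                         init = NULL, control = list(hessian = FALSE)) {
  B <- as.integer(B)
  stopifnot(B >= 1L)
  set.seed(seed)
  substreams <- sample.int(.Machine$integer.max, B)
  n <- n_subjects(cohort)
  if (is.null(init)) {
    base_fit <- fit_mle(cohort, model, control = control)
    init <- base_fit$theta
  }
  stat_fun <- if (length(formals(statistic)) >= 2L) statistic
              else function(fit, cohort) statistic(fit)
  reps <- list()
  n_fail <- 0L
  for (b in seq_len(B)) {
    set.seed(substreams[b])
    idx <- sample.int(n, n, replace = TRUE)
    val <- tryCatch({
      boot_cohort <- resample_cohort(cohort, idx)
      fit_b <- fit_mle(boot_cohort, model, init = init, control = control)
      if (!fit_b$convergence$converged) stop("replicate did not converge")
      as.numeric(stat_fun(fit_b, boot_cohort))
    }, error = function(e) NULL)
    if (is.null(val)) n_fail <- n_fail + 1L else reps[[length(reps) + 1L]] <- val
  }
  if (length(reps) == 0L) stop("all bootstrap replicates failed")
  mat <- do.call(rbind, reps)
  ci <- apply(mat, 2, stats::quantile, probs = c(0.025, 0.975), names = FALSE)
  rownames(ci) <- c("lo", "hi")
  fail_rate <- n_fail / B
  unreliable <- fail_rate > 0.2
  if (unreliable) {
    warning(sprintf("bootstrap CI unreliable: %.0f%% of replicates failed",
                    100 * fail_rate))
  }
  list(ci = ci, replicates = mat, B = B, seed = seed,
       substreams = substreams, n_fail = n_fail, fail_rate = fail_rate,
       unreliable = unreliable)
}
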