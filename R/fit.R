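#' Crude-rate starting values for the panel likelihood
#'
#' Data-driven initialisation: counts of observed interval transitions
#' divided by person-time at risk in the origin state (deaths attributed to
#' the last observed living state), floored at 1e-4 per person-year, on the
#' log scale. Covariate effects start at zero.
#'
#' @param cohort an `eldercohort`.
#' @param model an [intensity_model()] giving the transition structure.
#' @param floor_rate lower bound (per person-year) applied to crude rates
#'   before taking logs, keeping unobserved transitions finite.
#' @return Numeric parameter vector in the model's layout.
#' @export
crude_init <- function(cohort, model, floor_rate = 1e-4) {
  iv <- cohort_intervals(cohort, model)
  S <- model$nstates
  counts <- matrix(0, S, S)
  exposure <- numeric(S)
  for (i in seq_len(nrow(iv$ivl))) {
    r <- iv$ivl[i, "from"] + 1L
    exposure[r] <- exposure[r] + iv$dt[i]
    if (iv$ivl[i, "type"] == 1L) {
      counts[r, S] <- counts[r, S] + 1
    } else {
      s <- iv$ivl[i, "to"] + 1L
      if (s != r) counts[r, s] <- counts[r, s] + 1
    }
  }
  K <- nrow(model$transitions)
  logb <- numeric(K)
  for (k in seq_len(K)) {
    f <- model$transitions[k, 1] + 1L
    t <- model$transitions[k, 2] + 1L
    rate <- if (exposure[f] > 0) counts[f, t] / exposure[f] else 0
    logb[k] <- log(max(rate, floor_rate))
  }
  theta <- model_theta(model)
  theta[seq_len(K)] <- logb
  theta[-seq_len(K)] <- 0
  theta
}

#' Maximum-likelihood fit of the multistate intensity model
#'
#' Maximises the interval-censored panel log-likelihood by quasi-Newton
#' (BFGS) iteration with the analytic score, starting from crude interval
#' rates unless `init` is supplied. The observed-information covariance is
#' obtained by differencing the analytic score.
#'
#' @param cohort an `eldercohort`.
#' @param model an [intensity_model()] defining structure and covariates.
#' @param init optional starting parameter vector (model layout).
#' @param control list of optimizer settings: `maxit` (default 500),
#'   `reltol` (1e-10), `hessian` (TRUE).
#' @return An object of class `msm_fit` with the updated model, maximised
#'   log-likelihood, covariance, score, and convergence diagnostics
#'   including the accepted-step likelihood trace (non-decreasing).
#' @export
fit_mle <- function(cohort, model, init = NULL, control = list()) {
  ctl <- utils::modifyList(list(maxit = 500L, reltol = 1e-10, hessian = TRUE),
                           control)
  iv <- cohort_intervals(cohort, model)
  # warn when a free transition has no informing event
  counts <- table(factor(paste0(iv$ivl[, "from"], "->",
                                ifelse(iv$ivl[, "type"] == 1L,
                                       model$nstates - 1L, iv$ivl[, "to"]))))
  for (k in seq_len(nrow(model$transitions))) {
    key <- paste0(model$transitions[k, 1], "->", model$transitions[k, 2])
    if (!(key %in% names(counts))) {
      warning("no observed interval directly informing transition ", key)
    }
  }

  theta0 <- if (is.null(init)) crude_init(cohort, model) else as.numeric(init)
  cache <- new.env(parent = emptyenv())
  cache$trace <- numeric()
  eval_at <- function(theta) {
    if (!is.null(cache$theta) && identical(cache$theta, theta)) {
      return(cache$res)
    }
    res <- loglik_raw(model, theta, iv, want_grad = TRUE)
    res$total <- sum(sort(res$ll_subj))
    cache$theta <- theta
    cache$res <- res
    res
  }
  fn <- function(theta) {
    v <- eval_at(theta)$total
    cache$trace <- c(cache$trace, v)
    if (!is.finite(v)) return(1e12)
    -v
  }
  gr <- function(theta) {
    res <- eval_at(theta)
    if (!is.finite(res$total)) return(rep(0, length(theta)))
    -res$grad
  }
  ll0 <- sum(sort(loglik_raw(model, theta0, iv)$ll_subj))
  if (!is.finite(ll0)) {
    stop("non-finite log-likelihood at starting values; try crude-rate ",
         "initialization (crude_init) or a transition structure compatible ",
         "with the observed paths")
  }
  opt <- stats::optim(theta0, fn, gr, method = "BFGS",
                      control = list(maxit = ctl$maxit, reltol = ctl$reltol))
  theta_hat <- opt$par
  res_hat <- eval_at(theta_hat)
  ll_hat <- res_hat$total
  if (ll_hat < ll0 - 1e-8) {
    warning("optimizer ended below the starting log-likelihood; ",
            "keeping the starting values")
    theta_hat <- theta0
    res_hat <- eval_at(theta0)
    ll_hat <- res_hat$total
  }
  grad_hat <- res_hat$grad
  covar <- NULL
  if (isTRUE(ctl$hessian)) {
    H <- score_hessian(model, theta_hat, iv)
    covar <- tryCatch(solve(H), error = function(e) {
      warning("observed information is singular; covariance unavailable")
      matrix(NA_real_, length(theta_hat), length(theta_hat))
    })
  }
  nm <- theta_names(model)
  names(theta_hat) <- nm
  if (!is.null(covar)) dimnames(covar) <- list(nm, nm)
  # accepted-step trace: strictly improving evaluations
  tr <- cache$trace[is.finite(cache$trace)]
  accepted <- cummax(tr)[!duplicated(cummax(tr))]

  structure(
    list(model = set_theta(model, theta_hat), theta = theta_hat,
         loglik = ll_hat, loglik_init = ll0, covariance = covar,
         score = stats::setNames(grad_hat, nm),
         convergence = list(
           code = opt$convergence, converged = opt$convergence == 0L,
           message = if (is.null(opt$message)) "" else opt$message,
           gradient_norm = max(abs(grad_hat)), counts = opt$counts,
           trace = accepted),
         init = stats::setNames(theta0, nm), control = ctl,
         optimizer = "BFGS (stats::optim), analytic score",
         n_subjects = iv$n_subj, n_intervals = nrow(iv$ivl)),
    class = "msm_fit"
  )
}

# observed information: central differences of the analytic score
score_hessian <- function(model, theta, iv, h_rel = 1e-5) {
  p <- length(theta)
  H <- matrix(0, p, p)
  for (j in seq_len(p)) {
    h <- h_rel * (1 + abs(theta[j]))
    tp <- theta; tp[j] <- tp[j] + h
    tm <- theta; tm[j] <- tm[j] - h
    gp <- loglik_raw(model, tp, iv, want_grad = TRUE)$grad
    gm <- loglik_raw(model, tm, iv, want_grad = TRUE)$grad
    H[, j] <- -(gp - gm) / (2 * h)
  }
  (H + t(H)) / 2
}

#' @export
print.msm_fit <- function(x, ...) {
  cat("Multistate panel model fit (", x$model$structure, " structure)\n",
      sep = "")
  cat("  subjects:", x$n_subjects, "| intervals:", x$n_intervals, "\n")
  cat("  log-likelihood:", format(x$loglik), "\n")
  cat("  converged:", x$convergence$converged,
      "| max |score|:", format(x$convergence$gradient_norm, digits = 3), "\n")
  est <- summary_table(x)
  print(est, digits = 4)
  invisible(x)
}

#' Parameter summary with Wald intervals
#'
#' @param fit an `msm_fit`.
#' @return Data frame with estimate, standard error, and Wald 95% CI per
#'   parameter (log scale).
#' @export
summary_table <- function(fit) {
  se <- if (!is.null(fit$covariance)) sqrt(pmax(diag(fit$covariance), 0))
        else rep(NA_real_, length(fit$theta))
  data.frame(parameter = names(fit$theta), estimate = unname(fit$theta),
             se = unname(se),
             lo95 = unname(fit$theta - 1.96 * se),
             hi95 = unname(fit$theta + 1.96 * se),
             stringsAsFactors = FALSE)
}

#' @export
logLik.msm_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$theta), class = "logLik")
}

#' @export
coef.msm_fit <- function(object, ...) object$theta

#' @export
vcov.msm_fit <- function(object, ...) object$covariance

#' Serialize a fitted model to JSON
#'
#' @param fit an `msm_fit`.
#' @param path output path.
#' @param seed optional seed to record alongside the fit.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path, seed = NULL) {
  obj <- list(
    structure = fit$model$structure,
    age_form = fit$model$age_form,
    covariates = fit$model$covariates,
    transitions = apply(fit$model$transitions, 1,
                        function(r) paste0(r[1], "->", r[2])),
    parameters = as.list(fit$theta),
    loglik = fit$loglik,
    covariance = if (!is.null(fit$covariance)) unclass(fit$covariance),
    convergence = fit$convergence[c("code", "converged", "gradient_norm")],
    optimizer = fit$optimizer,
    n_subjects = fit$n_subjects,
    seed = seed
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
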