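#' Build the disability-onset analysis dataset
#'
#' Restricts to subjects with no disability at entry; mild and severe states
#' are combined into a single "any disability" event. The event time is the
#' age gap from entry to the first wave observed in state 1 or 2 (interval
#' right-endpoint convention); subjects who die or are lost while still
#' disability-free are censored at their last disability assessment.
#' Subjects disabled at entry, or with no follow-up assessment, are excluded
#' and tallied in the attached report.
#'
#' @param cohort an `eldercohort`.
#' @return Data frame of onset records (`id`, `time`, `event`, `entry_age`,
#'   covariates) with attribute `"report"` giving exclusion counts.
#' @export
prepare_onset_dataset <- function(cohort) {
  subj <- cohort$subjects
  obs <- cohort$observations[order(cohort$observations$id,
                                   cohort$observations$age), ]
  split_obs <- split(obs, obs$id)
  rows <- list()
  n_disabled_entry <- 0L
  n_no_followup <- 0L
  for (id in subj$id) {
    o <- split_obs[[id]]
    if (o$state[1] != 0L) {
      n_disabled_entry <- n_disabled_entry + 1L
      next
    }
    entry <- o$age[1]
    dis <- which(o$state %in% c(1L, 2L))
    if (length(dis) > 0) {
      time <- o$age[dis[1]] - entry
      event <- 1L
    } else {
      time <- o$age[nrow(o)] - entry
      event <- 0L
    }
    if (time <= 0) {
      n_no_followup <- n_no_followup + 1L
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      id = id, time = time, event = event, entry_age = entry,
      subj[subj$id == id, covariate_columns(), drop = FALSE],
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) stop("no disability-free entrants with follow-up")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "report") <- list(n_included = nrow(out),
                              n_disabled_at_entry = n_disabled_entry,
                              n_no_followup = n_no_followup)
  out
}

#' Add explicit missing-category dummies
#'
#' Recodes each requested categorical factor so that missing values become
#' their own `"missing"` level; no record is dropped for covariate
#' missingness (the missing-indicator convention for adjusted hazard
#' models).
#'
#' @param records onset records from [prepare_onset_dataset()].
#' @param factors character vector of factor columns (default: all model
#'   covariates present).
#' @return `records` with the factors releveled; reference levels are
#'   male, 0-year education, "others" marital status, non-smoker,
#'   non-drinker, no exercise, insufficient expenses, inadequate service,
#'   and no disease.
#' @export
missing_dummies <- function(records, factors = NULL) {
  lev <- covariate_levels()
  if (is.null(factors)) factors <- intersect(names(lev), names(records))
  for (v in factors) {
    x <- as.character(records[[v]])
    has_missing <- anyNA(x)
    x[is.na(x)] <- "missing"
    levels_v <- c(lev[[v]], if (has_missing) "missing")
    records[[v]] <- factor(x, levels = levels_v)
  }
  records
}

onset_model_covariates <- function(label) {
  switch(label,
         Model1 = character(),
         Model2 = c("entry_age", "sex", "region"),
         Model3 = c("entry_age", "sex", "region", "education", "marital",
                    "smoking", "drinking", "exercise", "expenses", "medical"),
         Model4 = c("entry_age", "sex", "region", "education", "marital",
                    "smoking", "drinking", "exercise", "expenses", "medical",
                    "diabetes", "heart_disease", "stroke"),
         stop("unknown model label ", label))
}

#' Cox proportional-hazards fit for disability onset
#'
#' Fits the partial likelihood by Newton iteration (via
#' [survival::coxph()]) with Breslow tie handling by default (wave-
#' synchronised times are heavily tied; Efron is selectable), on the
#' time-since-entry scale with age at entry as a covariate. Categorical
#' covariates are encoded with explicit missing-category dummies.
#'
#' @param records onset records from [prepare_onset_dataset()].
#' @param covariates character vector of covariate columns to adjust for.
#' @param ties `"breslow"` (default) or `"efron"`.
#' @param label model label stored with the fit.
#' @return An object of class `cox_fit`: coefficient/HR table with Wald 95%
#'   CIs, number of events, partial log-likelihood, convergence info, and
#'   the underlying `coxph` fit.
#' @export
fit_cox <- function(records, covariates, ties = c("breslow", "efron"),
                    label = "Model") {
  ties <- match.arg(ties)
  if (sum(records$event) < 1L) stop("no events in the onset dataset")
  records <- missing_dummies(records,
                             intersect(covariates, names(covariate_levels())))
  fml <- stats::as.formula(paste(
    "survival::Surv(time, event) ~",
    paste(covariates, collapse = " + ")))
  fit <- survival::coxph(fml, data = records, ties = ties,
                         control = survival::coxph.control(iter.max = 50))
  beta <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  if (any(!is.finite(se)) || any(abs(beta) > 15)) {
    warning("possible monotone-likelihood separation in covariate(s): ",
            paste(names(beta)[!is.finite(se) | abs(beta) > 15],
                  collapse = ", "))
  }
  tab <- data.frame(term = names(beta), coef = unname(beta),
                    se = unname(se), hr = exp(unname(beta)),
                    lo95 = exp(unname(beta - 1.96 * se)),
                    hi95 = exp(unname(beta + 1.96 * se)),
                    stringsAsFactors = FALSE)
  structure(
    list(label = label, table = tab, n = nrow(records),
         n_events = sum(records$event), ties = ties,
         loglik = fit$loglik[length(fit$loglik)],
         score_norm = tryCatch(
           max(abs(colSums(survival::coxph.detail(fit)$score))),
           error = function(e) NA_real_),
         converged = is.null(fit$iter) || fit$iter[1] < 50, coxph = fit),
    class = "cox_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Render the nested-model hazard-ratio table as aligned text
#'
#' @param suite output of [cox_model_suite()].
#' @return Character lines, invisibly; also printed. Reference rows print
#'   as 1.00 without an interval.
#' @export
format_cox_table <- function(suite) {
  lines <- sprintf("%-14s %-12s %-22s %-22s %-22s %-22s", "factor", "level",
                   "Model1", "Model2", "Model3", "Model4")
  for (i in seq_len(nrow(suite))) {
    cells <- vapply(paste0("Model", 1:4), function(m) {
      hr <- suite[[paste0(m, "_hr")]][i]
      lo <- suite[[paste0(m, "_lo")]][i]
      if (is.na(hr)) return("--")
      if (is.na(lo)) return("1.00")
      sprintf("%.2f (%.2f~%.2f)", hr, lo, suite[[paste0(m, "_hi")]][i])
    }, "")
    lines <- c(lines, sprintf("%-14s %-12s %-22s %-22s %-22s %-22s",
                              suite$factor[i], suite$level[i],
                              cells[1], cells[2], cells[3], cells[4]))
  }
  cat(lines, sep = "\n")
  invisible(lines)
}

#' @export
print.cox_fit <- function(x, ...) {
  cat("Cox onset model", x$label, "(", x$ties, "ties ) --", x$n_events,
      "events /", x$n, "records\n")
  print(x$table, digits = 4)
  invisible(x)
}

#' The four nested onset adjustment models
#'
#' Model1 fits each risk factor univariately; Model2 adds age, sex and
#' region; Model3 additionally education, marital status, smoking,
#' drinking, exercise, living expenses and medical service; Model4 further
#' adds diabetes, heart disease and stroke. Output is a factor-by-level
#' table of hazard ratios with reference rows fixed at 1.00.
#'
#' @param records onset records from [prepare_onset_dataset()].
#' @param factors risk factors to report (default: the standard set).
#' @param ties tie-handling method for all fits.
#' @return Data frame with columns `factor`, `level`, and per model `hr`,
#'   `lo95`, `hi95` (NA on reference rows' bounds, hr = 1).
#' @export
cox_model_suite <- function(records,
                            factors = c("sex", "education", "marital",
                                        "smoking", "drinking", "exercise",
                                        "expenses", "medical", "diabetes",
                                        "heart_disease", "stroke"),
                            ties = "breslow") {
  lev <- covariate_levels()
  fits <- list()
  for (m in c("Model2", "Model3", "Model4")) {
    covs <- unique(c(onset_model_covariates(m), factors))
    fits[[m]] <- fit_cox(records, covs, ties = ties, label = m)
  }
  out <- list()
  for (f in factors) {
    for (l in lev[[f]]) {
      ref <- l == lev[[f]][1]
      row <- data.frame(factor = f, level = l, stringsAsFactors = FALSE)
      for (m in c("Model1", "Model2", "Model3", "Model4")) {
        if (m == "Model1") {
          fit_m <- fit_cox(records, f, ties = ties, label = "Model1")
        } else {
          fit_m <- fits[[m]]
        }
        term <- paste0(f, l)
        hit <- match(term, fit_m$table$term)
        if (ref) {
          row[[paste0(m, "_hr")]] <- 1
          row[[paste0(m, "_lo")]] <- NA_real_
          row[[paste0(m, "_hi")]] <- NA_real_
        } else if (!is.na(hit)) {
          row[[paste0(m, "_hr")]] <- fit_m$table$hr[hit]
          row[[paste0(m, "_lo")]] <- fit_m$table$lo95[hit]
          row[[paste0(m, "_hi")]] <- fit_m$table$hi95[hit]
        } else {
          row[[paste0(m, "_hr")]] <- NA_real_
          row[[paste0(m, "_lo")]] <- NA_real_
          row[[paste0(m, "_hi")]] <- NA_real_
        }
      }
      out[[length(out) + 1L]] <- row
    }
  }
  do.call(rbind, out)
}
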