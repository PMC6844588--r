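pmm_code <- function(x, var) {
  match(x, covariate_levels()[[var]]) - 1
}
pmm_decode <- function(code, var) {
  covariate_levels()[[var]][round(code) + 1]
}

#' Multiple imputation by predictive mean matching
#'
#' Imputes missing baseline covariates m times. Each incomplete variable is
#' put on a numeric working coding (indicator for binaries, ordinal score
#' for education), regressed on the predictor set by least squares, and
#' each missing value is replaced by the observed value of a donor drawn
#' uniformly from the k nearest predicted-score neighbours — so every
#' imputed value is an observed, legal category. Variables are visited in a
#' fixed order; missing predictor entries are initialised by marginal draws
#' from the observed values and updated across `sweeps` passes.
#'
#' @param cohort an `eldercohort`.
#' @param m number of imputations (default 5).
#' @param k donor-pool size (default 5).
#' @param predictors covariate columns used as predictors (default: entry
#'   age plus all baseline covariates).
#' @param seed integer seed; the same seed reproduces the imputations
#'   bit-identically.
#' @param sweeps chained passes over the incomplete variables (default 1).
#' @return List of m completed `eldercohort`s, with attribute `"config"`
#'   recording m, k, predictors, seed and sweeps, and `"log"` noting any
#'   degenerate-regression fallbacks.
#' @export
impute_pmm <- function(cohort, m = 5L, k = 5L,
                       predictors = c("entry_age", covariate_columns()),
                       seed = 1L, sweeps = 1L) {
  stopifnot(m >= 1L, k >= 1L, sweeps >= 1L)
  subj <- cohort$subjects
  vars <- intersect(covariate_columns(), predictors)
  coded <- sapply(vars, function(v) pmm_code(subj[[v]], v))
  coded <- matrix(coded, nrow = nrow(subj),
                  dimnames = list(NULL, vars))
  num_pred <- setdiff(predictors, vars) # e.g. entry_age
  extra <- if (length(num_pred)) {
    as.matrix(subj[, num_pred, drop = FALSE])
  } else {
    NULL
  }
  incomplete <- vars[colSums(is.na(coded)) > 0]
  for (v in incomplete) {
    if (all(is.na(coded[, v]))) {
      stop("variable '", v, "' has no observed values; cannot impute")
    }
  }
  set.seed(seed)
  log_lines <- character()
  completed <- vector("list", m)
  for (i in seq_len(m)) {
    work <- coded
    for (v in incomplete) {
      miss <- is.na(work[, v])
      obs_vals <- work[!miss, v]
      work[miss, v] <- sample(obs_vals, sum(miss), replace = TRUE)
    }
    for (sw in seq_len(sweeps)) {
      for (v in incomplete) {
        miss <- is.na(coded[, v])
        y <- coded[, v]
        X <- cbind(extra, work[, setdiff(vars, v), drop = FALSE])
        keep_col <- apply(X, 2, function(col) stats::sd(col) > 0)
        X <- X[, keep_col, drop = FALSE]
        eta <- NULL
        if (ncol(X) > 0) {
          df <- data.frame(.y = y, X, check.names = TRUE)
          fit <- tryCatch(stats::lm(.y ~ ., data = df[!miss, , drop = FALSE]),
                          error = function(e) NULL)
          if (!is.null(fit)) {
            eta <- tryCatch(
              as.numeric(stats::predict(fit, newdata = df)),
              error = function(e) NULL)
          }
        }
        if (is.null(eta) || anyNA(eta)) {
          log_lines <- c(log_lines, paste0(
            "imputation ", i, ": degenerate regression for '", v,
            "'; marginal donor draw"))
          work[miss, v] <- sample(y[!miss], sum(miss), replace = TRUE)
          next
        }
        obs_idx <- which(!miss)
        for (j in which(miss)) {
          d <- abs(eta[j] - eta[obs_idx])
          donors <- obs_idx[order(d)][seq_len(min(k, length(obs_idx)))]
          pick <- donors[sample.int(length(donors), 1L)]
          work[j, v] <- y[pick]
        }
      }
    }
    si <- subj
    for (v in vars) si[[v]] <- pmm_decode(work[, v], v)
    ch <- cohort
    ch$subjects <- si
    completed[[i]] <- ch
  }
  attr(completed, "config") <- list(m = m, k = k, predictors = predictors,
                                    seed = seed, sweeps = sweeps)
  attr(completed, "log") <- log_lines
  completed
}

#' Pool results across imputations by entrywise mean
#'
#' Pools m result tables by the plain arithmetic mean, entry by entry (the
#' simple averaging convention; no between-imputation variance component is
#' propagated, unlike Rubin's rules — see the methods vignette).
#'
#' @param results list of m numeric vectors, matrices, or data frames of a
#'   common shape; non-numeric data-frame columns must agree across
#'   imputations and are carried through.
#' @return The pooled object, same shape as each input.
#' @export
pool_results <- function(results) {
  stopifnot(length(results) >= 1L)
  first <- results[[1]]
  if (is.data.frame(first)) {
    for (r in results[-1]) {
      if (!identical(dim(r), dim(first)) ||
          !identical(names(r), names(first))) {
        stop("imputation results have mismatching shapes")
      }
    }
    out <- first
    for (col in names(first)) {
      if (is.numeric(first[[col]])) {
        out[[col]] <- Reduce(`+`, lapply(results, `[[`, col)) / length(results)
      } else {
        for (r in results[-1]) {
          if (!identical(r[[col]], first[[col]])) {
            stop("non-numeric column '", col, "' differs across imputations")
          }
        }
      }
    }
    return(out)
  }
  if (!all(vapply(results, function(r) identical(dim(r), dim(first)) &&
                    length(r) == length(first), TRUE))) {
    stop("imputation results have mismatching shapes")
  }
  Reduce(`+`, results) / length(results)
}

#' Rubin's-rules pooling (opt-in alternative to the plain mean)
#'
#' Combines per-imputation point estimates and variances into the pooled
#' estimate, the total variance (within-imputation mean plus
#' (1 + 1/m) times the between-imputation variance), and its square root.
#' The package's default pooling is the plain mean ([pool_results()]);
#' this estimator additionally propagates imputation uncertainty.
#'
#' @param estimates m-row matrix (or list of vectors) of per-imputation
#'   point estimates.
#' @param variances matching per-imputation squared standard errors.
#' @return Data frame with `estimate`, `variance`, `se` per column.
#' @export
pool_rubin <- function(estimates, variances) {
  if (is.list(estimates)) estimates <- do.call(rbind, estimates)
  if (is.list(variances)) variances <- do.call(rbind, variances)
  stopifnot(identical(dim(estimates), dim(variances)))
  m <- nrow(estimates)
  qbar <- colMeans(estimates)
  ubar <- colMeans(variances)
  b <- if (m > 1) apply(estimates, 2, stats::var) else rep(0, ncol(estimates))
  total <- ubar + (1 + 1 / m) * b
  data.frame(estimate = qbar, variance = total, se = sqrt(total))
}

#' Write imputed cohorts as stacked long-format CSV
#'
#' @param imputations list returned by [impute_pmm()].
#' @param path output CSV path; rows carry an `imputation` column 1..m.
#' @return `path`, invisibly.
#' @export
write_imputed_csv <- function(imputations, path) {
  tmp <- tempfile(fileext = ".csv")
  on.exit(unlink(tmp), add = TRUE)
  parts <- lapply(seq_along(imputations), function(i) {
    write_panel(imputations[[i]], tmp)
    df <- utils::read.csv(tmp, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
    cbind(imputation = i, df)
  })
  utils::write.csv(do.call(rbind, parts), path, row.names = FALSE, na = "")
  invisible(path)
}
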