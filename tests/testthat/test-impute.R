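test_that("complete data pass through imputation unchanged", {
  g <- generate_cohort(simulation_scenario(
    n = 60, seed = 2, missing_rates = setNames(numeric(10),
                                               names(default_missing_rates()))))
  imp <- impute_pmm(g$cohort, m = 3, seed = 5)
  for (i in 1:3) expect_identical(imp[[i]]$subjects, g$cohort$subjects)
})

test_that("k = 1 imputes from the nearest predicted-score donor", {
  # 6-record toy solvable by exhaustive enumeration
  subjects <- data.frame(id = as.character(1:6), entry_age = c(65, 70, 75,
                                                               80, 85, 90),
                         death_age = NA_real_, stringsAsFactors = FALSE)
  for (v in covariate_columns()) subjects[[v]] <- NA_character_
  subjects$smoking <- c("no", "no", "yes", "yes", "yes", NA)
  obs <- data.frame(id = rep(subjects$id, each = 2),
                    age = rep(c(65, 68), 6), state = 0L,
                    stringsAsFactors = FALSE)
  cohort <- eldertrans:::new_cohort(subjects, obs)
  imp <- impute_pmm(cohort, m = 1, k = 1, predictors = c("entry_age",
                                                         "smoking"),
                    seed = 3)
  # oracle: least squares of the 0/1 smoking code on entry age, by hand
  y <- c(0, 0, 1, 1, 1)
  x <- c(65, 70, 75, 80, 85)
  b <- cov(x, y) / var(x)
  a <- mean(y) - b * mean(x)
  eta <- a + b * c(x, 90)
  donor <- which.min(abs(eta[6] - eta[1:5]))
  expect_identical(imp[[1]]$subjects$smoking[6], subjects$smoking[donor])
})

test_that("imputed values always lie in the observed support", {
  g <- generate_cohort(simulation_scenario(
    n = 150, seed = 6,
    missing_rates = setNames(rep(0.1, 10), names(default_missing_rates()))))
  imp <- impute_pmm(g$cohort, m = 5, k = 5, seed = 11)
  for (i in 1:5) {
    s <- imp[[i]]$subjects
    expect_false(anyNA(s[, names(default_missing_rates())]))
    for (v in names(default_missing_rates())) {
      observed <- unique(g$cohort$subjects[[v]][!is.na(g$cohort$subjects[[v]])])
      expect_true(all(s[[v]] %in% observed))
    }
  }
})

test_that("the same seed reproduces imputations bit-identically", {
  g <- generate_cohort(simulation_scenario(
    n = 80, seed = 7,
    missing_rates = setNames(rep(0.08, 10), names(default_missing_rates()))))
  i1 <- impute_pmm(g$cohort, m = 2, seed = 42)
  i2 <- impute_pmm(g$cohort, m = 2, seed = 42)
  expect_identical(i1[[1]]$subjects, i2[[1]]$subjects)
  expect_identical(i1[[2]]$subjects, i2[[2]]$subjects)
  i3 <- impute_pmm(g$cohort, m = 2, seed = 43)
  expect_false(identical(i1, i3))
})

test_that("pooling is the entrywise mean with shape checking", {
  r <- lapply(c(10, 12, 14, 16, 18), function(v) {
    data.frame(factor = "sex", level = "female", hr = v,
               stringsAsFactors = FALSE)
  })
  pooled <- pool_results(r)
  expect_identical(pooled$hr, 14)
  expect_identical(pool_results(r[1]), r[[1]])
  set.seed(1)
  expect_identical(pool_results(sample(r)), pooled)
  bad <- c(r[1:4], list(data.frame(other = 1)))
  expect_error(pool_results(bad), "mismatching shapes")
  # matrices pool the same way
  ms <- list(matrix(1:4, 2), matrix(5:8, 2))
  expect_identical(pool_results(ms), matrix(c(3, 4, 5, 6), 2))
})

test_that("Rubin's-rules pooling combines within and between variance", {
  est <- rbind(c(1.0, 2.0), c(1.2, 2.2), c(0.8, 1.8))
  v <- rbind(c(0.04, 0.09), c(0.04, 0.09), c(0.04, 0.09))
  p <- pool_rubin(est, v)
  expect_equal(p$estimate, c(1, 2))
  expect_equal(p$variance,
               c(0.04, 0.09) + (1 + 1 / 3) * apply(est, 2, var),
               tolerance = 1e-12)
  # m = 1: no between-imputation component
  p1 <- pool_rubin(est[1, , drop = FALSE], v[1, , drop = FALSE])
  expect_equal(p1$variance, c(0.04, 0.09))
})

test_that("a variable with no observed values cannot be imputed", {
  g <- generate_cohort(simulation_scenario(n = 30, seed = 9))
  g$cohort$subjects$stroke <- NA_character_
  expect_error(impute_pmm(g$cohort, m = 1, seed = 1), "no observed values")
})
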