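onset_toy <- function() {
  # 8 subjects, one binary covariate, heavy ties
  data.frame(
    id = letters[1:8],
    time = c(3, 3, 6, 6, 9, 9, 12, 12),
    event = c(1L, 1L, 1L, 0L, 1L, 1L, 0L, 1L),
    x = c(1, 0, 1, 0, 0, 1, 0, 1),
    stringsAsFactors = FALSE)
}

# independent oracle: Breslow partial log-likelihood, direct summation
breslow_loglik <- function(beta, d) {
  ll <- 0
  for (t in sort(unique(d$time[d$event == 1]))) {
    dead <- d$event == 1 & d$time == t
    risk <- d$time >= t
    ll <- ll + beta * sum(d$x[dead]) -
      sum(dead) * log(sum(exp(beta * d$x[risk])))
  }
  ll
}

test_that("Cox coefficients match brute-force partial-likelihood search", {
  d <- onset_toy()
  fit <- fit_cox(d, "x", ties = "breslow")
  grid <- seq(-3, 3, by = 1e-4)
  oracle <- grid[which.max(vapply(grid, breslow_loglik, 0, d = d))]
  expect_lt(abs(fit$table$coef[1] - oracle), 1e-4)
  # score at the optimum is numerically zero
  eps <- 1e-4
  deriv <- (breslow_loglik(fit$table$coef[1] + eps, d) -
              breslow_loglik(fit$table$coef[1] - eps, d)) / (2 * eps)
  expect_lt(abs(deriv), 1e-5)
})

test_that("partial likelihood is rank-invariant and symmetric", {
  d <- onset_toy()
  fit <- fit_cox(d, "x")
  d2 <- d
  d2$time <- d$time * 2 # affine rescaling of the time axis
  expect_equal(fit_cox(d2, "x")$table$coef, fit$table$coef,
               tolerance = 1e-10)
  d3 <- d[sample(nrow(d)), ] # subject reordering
  expect_equal(fit_cox(d3, "x")$table$coef, fit$table$coef,
               tolerance = 1e-10)
  # two identical groups with identical event patterns -> HR exactly 1
  d4 <- rbind(transform(d, x = 0), transform(d, x = 1,
                                             id = paste0(id, "2")))
  f4 <- fit_cox(d4, "x")
  expect_equal(f4$table$coef[1], 0, tolerance = 1e-8)
  expect_equal(f4$table$hr[1], 1, tolerance = 1e-8)
})

test_that("onset records follow the right-endpoint convention", {
  hs <- list(
    # 0 -> 0 -> 1: event at the first disabled wave, 6 years after entry
    subject_history("ev", c(70, 73, 76), c(0, 0, 1)),
    # 0 -> 0 then death: censored at the second wave's age gap
    subject_history("cens", c(70, 73), c(0, 0), death_age = 74.5),
    # disabled at entry: excluded and counted
    subject_history("excl", c(70, 73), c(1, 1)),
    # straight to severe counts as the combined any-disability event
    subject_history("sev", c(70, 73), c(0, 2)))
  for (h in seq_along(hs)) hs[[h]]$covariates <- list(sex = "male")
  cohort <- make_cohort(hs)
  rec <- prepare_onset_dataset(cohort)
  expect_identical(rec$time[rec$id == "ev"], 6)
  expect_identical(rec$event[rec$id == "ev"], 1L)
  expect_identical(rec$time[rec$id == "cens"], 3)
  expect_identical(rec$event[rec$id == "cens"], 0L)
  expect_identical(rec$time[rec$id == "sev"], 3)
  expect_identical(rec$event[rec$id == "sev"], 1L)
  expect_false("excl" %in% rec$id)
  expect_identical(attr(rec, "report")$n_disabled_at_entry, 1L)
})

test_that("onset inclusion reconciles with descriptive entry-state tallies", {
  g <- generate_cohort(simulation_scenario(n = 300, seed = 17))
  rec <- prepare_onset_dataset(g$cohort)
  rep <- attr(rec, "report")
  tab <- descriptive_table(g$cohort)
  entry0 <- sum(tab$n[tab$variable == "entry_state" &
                        tab$level == "no_disability"])
  entry_dis <- sum(tab$n[tab$variable == "entry_state" &
                           tab$level != "no_disability"])
  expect_identical(rep$n_disabled_at_entry, entry_dis)
  expect_identical(rep$n_included + rep$n_no_followup, entry0)
})

test_that("missing covariates become an explicit level, dropping no record", {
  d <- onset_toy()
  d$education <- c("0y", NA, "1-6y", "7+y", NA, "0y", "1-6y", "0y")
  enc <- missing_dummies(d, "education")
  expect_identical(nrow(enc), nrow(d))
  expect_true("missing" %in% levels(enc$education))
  expect_identical(sum(table(enc$education)), nrow(d))
  expect_identical(as.character(enc$education[2]), "missing")
  # no missing values -> encoding leaves the data unchanged up to type
  d2 <- onset_toy()
  d2$smoking <- rep(c("no", "yes"), 4)
  enc2 <- missing_dummies(d2, "smoking")
  expect_identical(as.character(enc2$smoking), d2$smoking)
  expect_false("missing" %in% levels(enc2$smoking))
})

test_that("the four nested models are estimable on simulated cohorts", {
  g <- generate_cohort(simulation_scenario(n = 400, seed = 23))
  rec <- prepare_onset_dataset(g$cohort)
  suite <- cox_model_suite(rec, factors = c("sex", "education", "smoking"))
  refs <- suite[suite$level %in% c("male", "0y", "no"), ]
  expect_true(all(refs$Model1_hr == 1))
  expect_true(all(refs$Model4_hr == 1))
  est <- suite[suite$factor == "sex" & suite$level == "female", ]
  expect_true(is.finite(est$Model2_hr) && est$Model2_hr > 0)
  expect_true(est$Model2_lo < est$Model2_hr & est$Model2_hr < est$Model2_hi)
})

test_that("proportional-hazards simulation recovers the true hazard ratio", {
  set.seed(90)
  hrs <- replicate(20, {
    n <- 1000
    x <- rbinom(n, 1, 0.5)
    t <- rexp(n, 0.1 * 1.5^x)
    cens <- runif(n, 2, 12)
    d <- data.frame(time = pmin(t, cens), event = as.integer(t <= cens),
                    x = x)
    fit_cox(d, "x")$table$hr[1]
  })
  expect_gt(mean(hrs), 1.35)
  expect_lt(mean(hrs), 1.65)
})
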