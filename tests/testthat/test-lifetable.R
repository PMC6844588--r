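test_that("exponential closed forms for life expectancy hold", {
  m <- surv_model(0.1)
  # effectively uncapped: TLE = 1/mu = 10
  ex <- state_expectancies(m, list(), index_age = 65, max_age = 265,
                           step = 0.25, survival_warn = 1.01)
  expect_equal(unname(ex$tle), 10, tolerance = 1e-3)
  # truncated at A = 30 years: (1 - exp(-mu A)) / mu
  ex30 <- suppressWarnings(
    state_expectancies(m, list(), index_age = 65, max_age = 95, step = 0.25))
  expect_equal(unname(ex30$tle), (1 - exp(-3)) / 0.1, tolerance = 1e-3)
  # truncation is flagged
  expect_warning(state_expectancies(m, list(), 65, max_age = 75),
                 "truncated")
})

test_that("expectancies match trajectory-averaged occupancy", {
  m <- const_model4(c(q01 = 0.15, q10 = 0.20, q12 = 0.10, q21 = 0.12,
                      q02 = 0.03, q20 = 0.04, q03 = 0.06, q13 = 0.10,
                      q23 = 0.20))
  ex <- state_expectancies(m, list(), index_age = 65, max_age = 165,
                           step = 0.25, survival_warn = 1.01)
  set.seed(77)
  for (r in 0:2) {
    sim <- simulate_occupancy(m, age = 65, state = r, horizon = 100,
                              n = 100000L)
    expect_lt(max(abs(ex$e[r + 1, ] - sim$mean_occupancy) /
                    pmax(sim$mean_occupancy, 0.05)), 0.02)
  }
})

test_that("better initial functional state never shortens toy life expectancy", {
  # monotone severity -> mortality gradient
  m <- const_model4(c(q01 = 0.10, q10 = 0.10, q12 = 0.10, q21 = 0.10,
                      q02 = 0.02, q20 = 0.02, q03 = 0.03, q13 = 0.10,
                      q23 = 0.30))
  ex <- state_expectancies(m, list(), 65, max_age = 200, step = 0.25,
                           survival_warn = 1.01)
  expect_gte(ex$tle[1], ex$tle[2])
  expect_gte(ex$tle[2], ex$tle[3])
})

test_that("life-table identities hold on randomized fitted-class models", {
  for (s in 1:5) {
    m <- random_model4(s + 100, lo = 0.02, hi = 0.3)
    ex <- state_expectancies(m, list(), 70, max_age = 200, step = 0.25,
                             survival_warn = 1.01)
    # additivity TLE = ND + MD + SD
    expect_lt(max(abs(rowSums(ex$e) - ex$tle)), 1e-6)
    q <- eldertrans:::lt_quantities(ex$e[1, ])
    expect_lt(abs(q["PND"] + q["PMD"] + q["PSD"] - 100), 0.1)
    expect_equal(unname(q["TLE"]), unname(q["ND"] + q["MD"] + q["SD"]),
                 tolerance = 1e-6)
    # halving the grid step moves every expectancy by < 0.5%
    ex2 <- state_expectancies(m, list(), 70, max_age = 200, step = 0.125,
                              survival_warn = 1.01)
    expect_lt(max(abs(ex2$e - ex$e) / pmax(abs(ex2$e), 1e-3)), 0.005)
    # uniformly increasing death intensities strictly decreases TLE
    m_hi <- m
    dn <- grep("3$", names(m$log_baselines))
    m_hi$log_baselines[dn] <- m$log_baselines[dn] + log(1.5)
    ex_hi <- state_expectancies(m_hi, list(), 70, max_age = 200,
                                step = 0.25, survival_warn = 1.01)
    expect_true(all(ex_hi$tle < ex$tle))
  }
})

test_that("zero disability intensities concentrate life in the entry state", {
  m <- intensity_model(transitions = rbind(c(0L, 3L), c(1L, 3L), c(2L, 3L)),
                       covariates = character(), age_form = "none",
                       log_baselines = log(rep(0.08, 3)))
  ex <- state_expectancies(m, list(), 65, max_age = 250, step = 0.25,
                           survival_warn = 1.01)
  expect_equal(unname(ex$e[1, 2:3]), c(0, 0), tolerance = 1e-10)
  q <- eldertrans:::lt_quantities(ex$e[1, ])
  expect_equal(unname(q["PND"]), 100, tolerance = 1e-8)
})

test_that("empirical initial distributions follow baseline frequencies", {
  spec <- data.frame(sex = rep("male", 3), region = rep("urban", 3),
                     state = 0:2, count = c(2145L, 1064L, 629L),
                     stringsAsFactors = FALSE)
  cohort <- counts_cohort(spec, entry_age = 65)
  pi0 <- empirical_initial_distribution(cohort, sex = "male",
                                        region = "urban", index_age = 65)
  expect_equal(round(unname(pi0), 3), c(0.559, 0.277, 0.164))
  # invariant to duplicating every subject
  dup <- cohort
  dup$subjects <- rbind(cohort$subjects,
                        transform(cohort$subjects,
                                  id = paste0(id, "dup")))
  dup$observations <- rbind(cohort$observations,
                            transform(cohort$observations,
                                      id = paste0(id, "dup")))
  expect_equal(empirical_initial_distribution(dup, "male", "urban", 65), pi0)
  # degenerate stratum
  one <- counts_cohort(data.frame(sex = "female", region = "rural",
                                  state = 0L, count = 5L))
  expect_equal(unname(empirical_initial_distribution(one, "female", "rural",
                                                     65)),
               c(1, 0, 0))
  expect_error(empirical_initial_distribution(cohort, "male", "urban", 90),
               "widen")
})

test_that("the assembled life table is tidy and internally consistent", {
  g <- generate_cohort(simulation_scenario(n = 500, seed = 14))
  m <- default_true_model()
  lt <- suppressWarnings(
    life_table(m, g$cohort, index_ages = c(70, 80), window = 5,
               max_age = 115, step = 0.5))
  expect_setequal(unique(lt$quantity), eldertrans:::lt_quantity_names())
  expect_setequal(unique(lt$initial_state),
                  c("population", "no_disability", "mild_disability",
                    "severe_disability"))
  wide <- lt[lt$quantity %in% c("TLE", "ND", "MD", "SD"), ]
  for (key in split(wide, paste(wide$sex, wide$region, wide$index_age,
                                wide$initial_state))) {
    est <- setNames(key$estimate, key$quantity)
    expect_equal(unname(est["TLE"]),
                 unname(est["ND"] + est["MD"] + est["SD"]),
                 tolerance = 1e-6)
  }
})
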