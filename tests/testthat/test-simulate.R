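test_that("degenerate simulations behave as designed", {
  m0 <- frozen_model()
  traj <- simulate_trajectory(m0, list(), entry_age = 70, entry_state = 1L,
                              horizon = 20)
  expect_identical(unique(traj$state), 1L)
  expect_equal(traj$age[nrow(traj)], 90)
  expect_error(simulate_trajectory(m0, list(), 70, 1L, horizon = Inf),
               "finite horizon")
})

test_that("death-only simulation reproduces the exponential mean", {
  m <- surv_model(0.2)
  set.seed(15)
  sim <- simulate_occupancy(m, age = 65, state = 0L, horizon = 200,
                            n = 100000L)
  expect_equal(sim$mean_lifetime, 5, tolerance = 0.05 / 5)
})

test_that("simulator and matrix-exponential one-year frequencies agree", {
  # the keystone cross-check tying simulation and analytic halves together
  m <- const_model4(c(q01 = 0.20, q10 = 0.25, q12 = 0.12, q21 = 0.10,
                      q02 = 0.04, q20 = 0.05, q03 = 0.06, q13 = 0.10,
                      q23 = 0.18))
  P <- transition_probability(m, list(), 70, 71)
  n <- 200000L
  set.seed(33)
  for (r in 0:2) {
    sim <- simulate_occupancy(m, age = 70, state = r, horizon = 1.5, n = n,
                              record_t = 1)
    se <- sqrt(P[r + 1, ] * (1 - P[r + 1, ]) / n)
    expect_true(all(abs(sim$state_at - P[r + 1, ]) <= 3 * se + 1e-12))
  }
})

test_that("trajectories never continue past death", {
  scen <- simulation_scenario(n = 150, seed = 19)
  for (i in 1:25) {
    prof <- list(female = rbinom(1, 1, 0.5), rural = rbinom(1, 1, 0.5))
    traj <- simulate_trajectory(scen$model, prof, entry_age = 80,
                                entry_state = 2L, horizon = 30)
    died <- which(traj$state == 3L)
    if (length(died)) expect_identical(died, nrow(traj))
    expect_true(all(diff(traj$age) > 0))
  }
})

test_that("wave sampling honours the survey design", {
  waves <- c(65, 68, 71, 74, 77)
  alive <- data.frame(age = c(65, 80), state = c(0L, 0L))
  sw <- sample_waves(alive, waves, dropout = 0)
  expect_identical(sw$obs_ages, waves)
  expect_identical(sw$obs_states, rep(0L, 5))
  expect_true(is.na(sw$death_age))
  expect_false(sw$excluded)

  # death between waves 2 and 3: two observations plus the exact death age
  dead <- data.frame(age = c(65, 69.4), state = c(1L, 3L))
  sw2 <- sample_waves(dead, waves, dropout = 0)
  expect_identical(sw2$obs_ages, waves[1:2])
  expect_identical(sw2$death_age, 69.4)
  expect_false(sw2$excluded)

  # certain dropout after the first wave: flagged for exclusion
  set.seed(3)
  sw3 <- sample_waves(alive, waves, dropout = 1)
  expect_identical(sw3$obs_ages, waves[1])
  expect_true(sw3$excluded)

  # death after the last attended contact is never ascertained
  late <- data.frame(age = c(65, 78.5), state = c(0L, 3L))
  sw4 <- sample_waves(late, waves, dropout = 0)
  expect_true(is.na(sw4$death_age))
  expect_identical(sw4$obs_ages, waves)
})

test_that("generation is seed-deterministic and matches its design", {
  scen <- simulation_scenario(n = 400, seed = 27)
  g1 <- generate_cohort(scen)
  g2 <- generate_cohort(scen)
  expect_identical(g1$cohort, g2$cohort)
  expect_identical(g1$truth$theta, g2$truth$theta)

  # entry-state frequencies approximate the scenario's distribution
  first <- g1$cohort$observations[!duplicated(g1$cohort$observations$id), ]
  subj <- g1$cohort$subjects
  um <- subj$id[subj$sex == "male" & subj$region == "urban"]
  p_hat <- tabulate(first$state[first$id %in% um] + 1L, 3) / length(um)
  p <- scen$entry_state_probs["male|urban", ]
  se <- sqrt(p * (1 - p) / length(um))
  expect_true(all(abs(p_hat - p) <= 3 * se + 1e-12))

  # death ages strictly exceed the last living observation
  has_death <- !is.na(subj$death_age)
  last_obs <- vapply(split(g1$cohort$observations$age,
                           g1$cohort$observations$id), max, 1)
  expect_true(all(subj$death_age[has_death] >
                    last_obs[subj$id[has_death]]))
})

test_that("the ground-truth sidecar is internally consistent", {
  scen <- simulation_scenario(n = 50, seed = 4)
  g <- generate_cohort(scen, truth_sim_n = 4000L, truth_horizon = 50)
  lt <- g$truth$lifetable[["male|urban"]]
  expect_equal(lt$TLE, lt$ND + lt$MD + lt$SD, tolerance = 1e-9)
  # trajectory-averaged truth agrees with the analytic estimator at the
  # true parameters within Monte-Carlo error
  ex <- state_expectancies(scen$model, list(female = 0, rural = 0),
                           index_age = 65, max_age = 115, step = 0.25,
                           survival_warn = 1.01)
  expect_lt(abs(lt$TLE - ex$tle[1]) / ex$tle[1], 0.05)
  path <- withr::local_tempfile(fileext = ".json")
  write_truth_json(g$truth, path)
  back <- jsonlite::read_json(path)
  expect_equal(back$seed, 4L)
  expect_length(back$theta, length(eldertrans:::model_theta(scen$model)))
})
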