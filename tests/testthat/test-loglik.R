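test_that("frozen and closed-form likelihood contributions are exact", {
  # frozen chain: no allowed transitions, two observations in the same state
  m0 <- frozen_model()
  expect_identical(subject_loglik(m0, subject_history("a", c(65, 70), c(1, 1))),
                   0)
  # alive at a, death at d under constant rate: log(exp(-l (d-a)) * l)
  lam <- 0.37
  m <- surv_model(lam)
  ll <- subject_loglik(m, subject_history("a", 2, 0, death_age = 5.5))
  expect_equal(ll, -lam * 3.5 + log(lam), tolerance = 1e-10)
})

test_that("structurally impossible paths yield -Inf with a diagnostic", {
  m <- intensity_model(transitions = rbind(c(0L, 1L), c(0L, 3L), c(1L, 3L)),
                       covariates = character(), age_form = "none",
                       log_baselines = log(c(0.2, 0.05, 0.1)))
  ll <- subject_loglik(m, subject_history("a", c(65, 68), c(1, 0)))
  expect_identical(as.numeric(ll), -Inf)
  expect_match(attr(ll, "impossible"), "impossible transition 1->0")
})

test_that("panel likelihood matches Monte-Carlo path probabilities", {
  m <- const_model4(c(q01 = 0.20, q10 = 0.25, q12 = 0.15, q21 = 0.10,
                      q02 = 0.05, q20 = 0.05, q03 = 0.05, q13 = 0.08,
                      q23 = 0.15))
  # living-only observed path 0 -> 1 -> 1 at ages 70, 72, 75; by the Markov
  # property its probability factors into the two interval marginals, each
  # estimated from simulated trajectories
  ll <- subject_loglik(m, subject_history("a", c(70, 72, 75), c(0, 1, 1)))
  n <- 200000L
  set.seed(42)
  s1 <- simulate_occupancy(m, age = 70, state = 0L, horizon = 2.5, n = n,
                           record_t = 2)
  s2 <- simulate_occupancy(m, age = 72, state = 1L, horizon = 3.5, n = n,
                           record_t = 3)
  p1 <- s1$state_at[2] # in state 1 at +2y from state 0
  p2 <- s2$state_at[2] # still state 1 at +3y from state 1
  se_log <- sqrt((1 - p1) / (p1 * n) + (1 - p2) / (p2 * n))
  expect_lt(abs(as.numeric(ll) - log(p1 * p2)), 3 * se_log)
})

test_that("total log-likelihood is invariant to subject order and labels", {
  g <- generate_cohort(simulation_scenario(n = 120, seed = 3))
  m <- default_true_model()
  ll1 <- as.numeric(cohort_loglik(m, g$cohort))
  shuffled <- g$cohort
  set.seed(11)
  perm <- sample(nrow(shuffled$subjects))
  shuffled$subjects <- shuffled$subjects[perm, ]
  relabel <- setNames(sprintf("z%04d", rev(seq_len(nrow(shuffled$subjects)))),
                      shuffled$subjects$id)
  shuffled$subjects$id <- unname(relabel[shuffled$subjects$id])
  shuffled$observations$id <- unname(relabel[shuffled$observations$id])
  expect_identical(as.numeric(cohort_loglik(m, shuffled)), ll1)
})

test_that("the analytic score matches numerical differentiation", {
  g <- generate_cohort(simulation_scenario(n = 50, seed = 21))
  m <- default_true_model()
  iv <- eldertrans:::cohort_intervals(g$cohort, m)
  th <- eldertrans:::model_theta(m)
  gr <- eldertrans:::loglik_raw(m, th, iv, want_grad = TRUE)$grad
  num <- vapply(seq_along(th), function(j) {
    e <- rep(0, length(th)); e[j] <- 1e-6
    (sum(eldertrans:::loglik_raw(m, th + e, iv)$ll_subj) -
       sum(eldertrans:::loglik_raw(m, th - e, iv)$ll_subj)) / 2e-6
  }, 0)
  expect_lt(max(abs(gr - num)), 1e-5)
})
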