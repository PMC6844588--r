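test_that("intensities follow the log-linear covariate model", {
  m <- intensity_model("full", covariates = c("female", "rural"),
                       age_form = "none")
  # all betas zero, every baseline 0.1 -> every allowed off-diagonal 0.1
  Q <- build_Q(m, list(female = 1, rural = 1))
  off <- Q[row(Q) != col(Q)]
  expect_equal(off[off > 0], rep(0.1, 9), tolerance = 1e-14,
               ignore_attr = TRUE)
  expect_true(all(Q[4, ] == 0)) # death row

  # a rural log-effect of log(2) on one arrow exactly doubles that arrow
  m2 <- m
  m2$betas["q12", "rural"] <- log(2)
  Qu <- build_Q(m2, list(female = 0, rural = 0))
  Qr <- build_Q(m2, list(female = 0, rural = 1))
  expect_equal(Qr[2, 3], 2 * Qu[2, 3], tolerance = 1e-14)
  keep <- !(row(Qu) == 2 & col(Qu) %in% c(2, 3))
  expect_equal(Qr[keep], Qu[keep], tolerance = 1e-14)
})

test_that("built intensity matrices have zero row sums for random draws", {
  for (s in 1:20) {
    set.seed(s)
    betas <- cbind(rnorm(9, 0, 0.05), rnorm(9, 0, 0.2), rnorm(9, 0, 0.2))
    m <- intensity_model("full", covariates = c("female", "rural"),
                         age_form = "loglinear",
                         log_baselines = log(runif(9, 0.001, 1)),
                         betas = betas)
    Q <- build_Q(m, list(female = rbinom(1, 1, 0.5),
                         rural = rbinom(1, 1, 0.5)),
                 age = runif(1, 65, 95))
    expect_lt(max(abs(rowSums(Q))), 1e-12)
    expect_true(all(Q[row(Q) != col(Q)] >= 0))
  }
})

test_that("missing model covariates are refused with imputation advice", {
  m <- intensity_model("full", covariates = c("female", "rural"),
                       age_form = "none")
  expect_error(build_Q(m, list(female = 1)), "impute")
})

test_that("transition probabilities satisfy the defining cases", {
  # zero elapsed time -> identity
  m <- surv_model(0.5)
  expect_identical(transition_probability(m, list(), 70, 70), diag(2),
                   ignore_attr = TRUE)
  # alive->dead at 0.5/yr over one year: P(alive, alive) = exp(-0.5)
  P <- transition_probability(m, list(), 0, 1)
  expect_equal(P[1, 1], exp(-0.5), tolerance = 1e-12)

  # random constant 4-state Q over t = 2 vs the discretized-chain oracle
  m4 <- random_model4(31, lo = 0.01, hi = 0.08)
  Q <- build_Q(m4)
  P <- transition_probability(m4, list(), 70, 72)
  step <- diag(4) + Q * 2 / 2^16
  D <- step
  for (i in 1:16) D <- D %*% D
  expect_lt(max(abs(P - D)), 1e-6)
})

test_that("every produced transition matrix is row-stochastic", {
  for (s in 1:10) {
    set.seed(s)
    m <- intensity_model("full", covariates = c("female", "rural"),
                         age_form = "loglinear",
                         log_baselines = log(runif(9, 0.001, 0.6)),
                         betas = matrix(rnorm(27, 0, 0.15), 9, 3))
    m$betas[, "age"] <- abs(m$betas[, "age"]) / 4
    P <- transition_probability(m, list(female = 1, rural = 0),
                                65 + 10 * runif(1), 80 + 10 * runif(1))
    expect_lt(max(abs(rowSums(P) - 1)), 1e-10)
    expect_true(all(P >= 0 & P <= 1))
    expect_equal(P[4, 4], 1, tolerance = 1e-12)
  }
})

test_that("annual probabilities match the general machinery and cap extrapolation", {
  m4 <- random_model4(7)
  P1 <- annual_probability(m4, list(), age = 72)
  P2 <- transition_probability(m4, list(), 72, 73)
  expect_equal(P1, P2, tolerance = 1e-12)
  expect_warning(annual_probability(m4, list(), age = 150), "capped")
})
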