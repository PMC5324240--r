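test_that("seeded simulation is exactly reproducible", {
  d <- continuous_to_discrete(design_1d())
  plan <- simulation_plan(100, seed = 42)
  r1 <- simulate_cohort(d, plan)
  r2 <- simulate_cohort(d, plan)
  expect_identical(as.data.frame(r1), as.data.frame(r2))

  p <- design_td()
  planj <- simulation_plan(50, mode = "jittered", seed = 42)
  expect_identical(as.data.frame(simulate_cohort(p, planj)),
                   as.data.frame(simulate_cohort(p, planj)))
})

test_that("jittered intervals stay within ten percent of the step", {
  p <- continuous_params(a = -0.05, f1 = 80, b = 2.5, Q = 0, f = 80, mu0 = 1e-4)
  plan <- simulation_plan(40, t_start = 30, t_max = 60, step = 1,
                          mode = "jittered", seed = 13)
  rec <- simulate_cohort(p, plan)
  dt <- rec$t2 - rec$t1
  expect_true(all(dt >= 0.9 - 1e-12 & dt <= 1.1 + 1e-12))
})

test_that("a null hazard censors everyone at the maximum age", {
  p <- continuous_params(a = -0.05, f1 = 80, b = 5, Q = 0, f = 80, mu0 = 0)
  plan <- simulation_plan(50, t_start = 30, t_max = 105, seed = 3)
  rec <- simulate_cohort(p, plan)
  expect_equal(sum(rec$event), 0)
  last <- !duplicated(rec$id, fromLast = TRUE)
  expect_true(all(rec$t2[last] == 105))
  # max_obs caps follow-up instead
  plan5 <- simulation_plan(20, t_start = 30, t_max = 105, max_obs = 5, seed = 3)
  rec5 <- simulate_cohort(p, plan5)
  expect_true(all(table(rec5$id) == 5))
})

test_that("with zero hazard the process is mean-reverting to f1", {
  # long-run mean f1 and variance -b^2/(2a) for the continuous-time model
  p <- continuous_params(a = -0.05, f1 = 80, b = 5, Q = 0, f = 80, mu0 = 0)
  plan <- simulation_plan(400, t_start = 0, t_max = 120, step = 1, seed = 77,
                          sigma0 = 1)
  rec <- simulate_cohort(p, plan)
  lateY <- rec$V1[rec$t1 > 80]
  vstat <- -25 / (2 * -0.05)
  # within-subject autocorrelation (timescale 1/|2a| = 10 years) leaves
  # roughly two effective draws per subject in the 40-year tail window
  expect_lt(abs(mean(lateY) - 80), 3 * sqrt(vstat / (2 * 400)))
  expect_lt(abs(var(lateY) / vstat - 1), 0.10)
})

test_that("simulated survival matches the Gompertz closed form when Q = 0", {
  p <- continuous_params(a = -0.05, f1 = 80, b = 5, Q = 0, f = 80,
                         mu0 = 1e-5, theta = 0.1, exp_theta = TRUE)
  plan <- simulation_plan(5000, t_start = 0, t_max = 105, step = 1, seed = 19)
  rec <- simulate_cohort(p, plan)
  last <- !duplicated(rec$id, fromLast = TRUE)
  tau <- rec$t2[last]
  S_hat <- function(t) mean(tau > t)   # censoring happens only at t_max
  S_true <- function(t) exp(-1e-5 / 0.1 * (exp(0.1 * t) - 1))
  for (t in c(40, 70, 90)) {
    se <- sqrt(S_true(t) * (1 - S_true(t)) / 5000)
    expect_lt(abs(S_hat(t) - S_true(t)), 3 * se)
  }
})

test_that("the product-limit estimator reproduces hand computations", {
  # three deaths, no censoring
  km <- kaplan_meier(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$surv, c(2 / 3, 1 / 3, 0))
  # everyone censored
  km2 <- kaplan_meier(c(1, 2, 3), c(0, 0, 0))
  expect_true(all(km2$surv == 1))
  # mixed: censored at 1, deaths at 2, 2, censored at 3
  # S(2) = (3 - 2)/3 = 1/3 by the product limit
  km3 <- kaplan_meier(c(1, 2, 2, 3), c(0, 1, 1, 0))
  expect_equal(km3$surv[km3$time == 2], 1 / 3)
  # survival nonincreasing with a confidence band
  expect_true(all(diff(km3$surv) <= 0))
  expect_true(all(km3$lower <= km3$surv & km3$surv <= km3$upper))
  expect_error(kaplan_meier(numeric(0), numeric(0)), "empty")
})

test_that("projection summarizes initialization and monotone survival", {
  d <- continuous_to_discrete(design_1d())
  plan <- simulation_plan(1500, t_start = 30, t_max = 105, seed = 23)
  pr <- project(d, plan, initial_mean = 80, initial_sd = 1)
  mb <- pr$summary$mean_by_age
  expect_lt(abs(mb$V1[mb$age == 30] - 80), 3 * 1 / sqrt(1500))
  s <- pr$summary$survival
  expect_true(all(diff(s$surv) <= 1e-12))
  expect_true(all(s$time > 30))
  expect_equal(mb$n_at_risk[mb$age == 30], 1500)
})

test_that("projected survival agrees with the marginal-hazard integral", {
  # population run of the moment equations: survival exp(-H(t)) must track
  # the Kaplan-Meier curve of a simulated cohort within its band
  pth <- design_1d()
  pth$exp_theta <- TRUE   # Gompertz scaling of mu0 and Q, as in the hazard
  plan <- simulation_plan(5000, t_start = 30, t_max = 105, seed = 29)
  pr <- project(pth, plan, initial_mean = 80, initial_sd = 1)
  s <- pr$summary$survival
  st <- moment_state(80, matrix(1, 1, 1))
  ages <- seq(40, 90, by = 10)
  H <- numeric(length(ages))
  t0 <- 30
  for (i in seq_along(ages)) {
    st <- propagate_moments(pth, st, t0, ages[i])
    H[i] <- st$H
    t0 <- ages[i]
  }
  S_model <- exp(-H)
  for (i in seq_along(ages)) {
    row <- max(which(s$time <= ages[i])) # step function: last jump before age
    expect_gt(S_model[i], s$lower[row] - 0.02)
    expect_lt(S_model[i], s$upper[row] + 0.02)
  }
})
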