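test_that("the marginal hazard matches its closed form", {
  p <- continuous_params(a = -0.05, f1 = 80, b = 5, Q = 1e-6, f = 80, mu0 = 1e-5)
  # at the risk minimum with zero spread the marginal hazard is mu0
  expect_equal(marginal_hazard(p, moment_state(80, matrix(0, 1, 1)), 40), 1e-5)
  # substitution: mu0 + Q (m-f)^2 + Q gamma
  expect_equal(marginal_hazard(p, moment_state(90, matrix(25, 1, 1)), 40),
               1e-5 + 1e-4 + 2.5e-5)
  # with no risk sensitivity the hazard is the baseline whatever the state
  p0 <- continuous_params(a = -0.05, f1 = 80, b = 5, Q = 0, f = 80, mu0 = 3e-4)
  expect_equal(marginal_hazard(p0, moment_state(123, matrix(50, 1, 1)), 40), 3e-4)
  expect_error(marginal_hazard(p, moment_state(c(1, 2)), 40), "dimension")
})

test_that("moment propagation matches scalar closed forms on a parameter grid", {
  # with Q = 0 the moment equations decouple:
  # m(t) = f1 + (m0 - f1) e^{a t},  gamma(t) = -b^2/(2a) (1 - e^{2 a t})
  for (a in c(-0.02, -0.05, -0.2)) {
    for (b in c(1, 5)) {
      for (f1 in c(60, 100)) {
        p <- continuous_params(a = a, f1 = f1, b = b, Q = 0, f = 80, mu0 = 1e-5)
        st <- propagate_moments(p, moment_state(90, matrix(0, 1, 1)), 0, 10)
        m_exact <- f1 + (90 - f1) * exp(a * 10)
        g_exact <- -b^2 / (2 * a) * (1 - exp(2 * a * 10))
        expect_equal(st$m, m_exact, tolerance = 1e-6)
        expect_equal(st$gamma[1, 1], g_exact, tolerance = 1e-6)
        # constant-hazard accumulation: H = mu0 * span when Q = 0
        expect_equal(st$H, 1e-5 * 10, tolerance = 1e-10)
      }
    }
  }
  # equilibrium: b = 0, Q = 0, m0 = f1 keeps the state constant
  pe <- continuous_params(a = -0.05, f1 = 80, b = 0, Q = 0, f = 80, mu0 = 0)
  ste <- propagate_moments(pe, moment_state(80, matrix(0, 1, 1)), 30, 45)
  expect_equal(ste$m, 80)
  expect_equal(ste$gamma[1, 1], 0)
})

test_that("gamma stays symmetric and positive semi-definite along 2D integrations", {
  set.seed(31)
  p <- design_2d()
  st <- moment_state(c(95, 190), diag(c(4, 9)))
  for (i in 1:10) {
    st <- propagate_moments(p, st, 30 + (i - 1) * 2, 30 + i * 2)
    expect_lt(max(abs(st$gamma - t(st$gamma))), 1e-9)
    expect_gt(min(eigen(st$gamma, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
  }
  # H nondecreasing
  expect_gte(st$H, 0)
})

test_that("subject likelihood has the published structure", {
  p <- continuous_params(a = -0.05, f1 = 80, b = 5, Q = 1e-6, f = 80,
                         mu0 = 1e-5, theta = 0.1, exp_theta = TRUE)
  # censored vs dead at identical data differ by exactly log(mubar(tau))
  base <- data.frame(id = 1, event = 0, t1 = c(50, 52), t2 = c(52, 60),
                     V1 = c(82, 85))
  dead <- base; dead$event <- c(0, 1)
  ll0 <- subject_log_likelihood(p, longitudinal_records(base, "V1"),
                                init_mean = 80, init_cov = matrix(25, 1, 1))
  ll1 <- subject_log_likelihood(p, longitudinal_records(dead, "V1"),
                                init_mean = 80, init_cov = matrix(25, 1, 1))
  st <- propagate_moments(p, moment_state(85), 52, 60)
  expect_equal(ll1 - ll0, log(marginal_hazard(p, st, 60)), tolerance = 1e-10)

  # an observation equal to the propagated mean leaves only the
  # normalization term
  st1 <- propagate_moments(p, moment_state(82), 50, 52)
  hit <- data.frame(id = 1, event = 0, t1 = c(50, 52), t2 = c(52, 52.5),
                    V1 = c(82, st1$m))
  llh <- subject_log_likelihood(p, longitudinal_records(hit, "V1"),
                                init_mean = 82, init_cov = matrix(1e-8, 1, 1))
  st2 <- propagate_moments(p, moment_state(st1$m, H = st1$H), 52, 52.5)
  expect_equal(llh - (-0.5 * log(2 * pi * st1$gamma[1, 1]) - st2$H) -
                 dnorm(82, 82, 1e-4, log = TRUE), 0, tolerance = 1e-8)

  # follow-up ending before the measurement is flagged on ingestion
  bad <- data.frame(id = 1, event = 0, t1 = c(50, 52), t2 = c(52, 51.5), V1 = c(82, 85))
  expect_warning(longitudinal_records(bad, "V1"), "t2 > t1")
})

test_that("compiled and reference likelihoods agree and are permutation-invariant", {
  set.seed(5)
  p <- continuous_params(a = -0.05, f1 = 80, b = 2.5, Q = 1e-5, f = 80, mu0 = 0.05)
  plan <- simulation_plan(60, t_start = 30, t_max = 105, step = 1,
                          mode = "jittered", seed = 5)
  rec <- simulate_cohort(p, plan)
  flat <- qhspm:::flatten_records(rec)
  ll_cpp <- spm_log_likelihood(p, rec)
  df <- as.data.frame(rec)
  ll_r <- sum(vapply(split(df, df$id), function(s)
    subject_log_likelihood(p, longitudinal_records(s, "V1"),
                           init_mean = flat$init_mean,
                           init_cov = flat$init_cov), numeric(1)))
  expect_equal(ll_cpp, ll_r, tolerance = 1e-10)

  # permutation invariance over subjects
  perm <- df[order(match(df$id, sample(unique(df$id)))), ]
  ll_perm <- spm_log_likelihood(p, longitudinal_records(perm, "V1"))
  expect_equal(ll_perm, ll_cpp, tolerance = 1e-10)
})

test_that("halving the integration substep leaves the likelihood unchanged", {
  set.seed(6)
  p <- design_td()
  plan <- simulation_plan(100, t_start = 30, t_max = 105, step = 1,
                          mode = "jittered", seed = 6)
  rec <- simulate_cohort(p, plan)
  ll1 <- spm_log_likelihood(p, rec, hmax = 0.05)
  ll2 <- spm_log_likelihood(p, rec, hmax = 0.025)
  expect_lt(abs(ll1 - ll2), 1e-6)
})

test_that("the likelihood dominates at the generating parameters", {
  set.seed(8)
  p <- continuous_params(a = -0.05, f1 = 80, b = 2.5, Q = 1e-5, f = 80, mu0 = 0.05)
  plan <- simulation_plan(400, t_start = 30, t_max = 105, step = 1,
                          mode = "jittered", seed = 8)
  rec <- simulate_cohort(p, plan)
  ll_true <- spm_log_likelihood(p, rec)
  worse <- p
  worse$Q <- p$Q * 1.5
  expect_gt(ll_true, spm_log_likelihood(worse, rec))
})

test_that("constant-coefficient fitting is self-consistent", {
  set.seed(14)
  truth <- continuous_params(a = -0.05, f1 = 80, b = 2.5, Q = 1e-5, f = 80,
                             mu0 = 0.05)
  plan <- simulation_plan(500, t_start = 30, t_max = 105, step = 1,
                          mode = "jittered", seed = 14)
  rec <- simulate_cohort(truth, plan)
  fit <- fit_continuous(rec, maxit = 2000L)
  expect_equal(fit$convergence, 0)
  # the fit must beat the truth in likelihood (it is the MLE)
  expect_gte(fit$loglik, spm_log_likelihood(truth, rec,
                                            init_mean = fit$init_mean,
                                            init_cov = fit$init_cov) - 1e-4)
  # headline dynamics parameters recovered to sampling accuracy
  expect_equal(fit$params$a[1, 1], -0.05, tolerance = 0.4)
  expect_equal(fit$params$f1, 80, tolerance = 0.05)
  expect_equal(fit$params$b, 2.5, tolerance = 0.1)
})

test_that("a degenerate time-dependent specification reduces to the constant fit", {
  set.seed(15)
  truth <- continuous_params(a = -0.05, f1 = 80, b = 2.5, Q = 1e-5, f = 80,
                             mu0 = 0.05)
  plan <- simulation_plan(150, t_start = 30, t_max = 105, step = 1,
                          mode = "jittered", seed = 15)
  rec <- simulate_cohort(truth, plan)
  f_const <- fit_continuous(rec, start = truth, maxit = 1200L, restarts = 0L)
  f_td <- fit_time_dependent(rec, formulas = character(0), start = truth,
                             maxit = 1200L, restarts = 0L)
  expect_equal(f_td$loglik, f_const$loglik, tolerance = 1e-6)
  expect_equal(f_td$params$a[1, 1], f_const$params$a[1, 1], tolerance = 1e-4)

  # k > 1 with slopes is refused
  rec2 <- simulate_cohort(continuous_to_discrete(design_2d()),
                          simulation_plan(30, seed = 2))
  expect_error(fit_time_dependent(rec2), "one covariate")
})

test_that("slope-only estimation recovers a linear trend in the mean", {
  set.seed(16)
  truth <- design_td()
  plan <- simulation_plan(400, t_start = 30, t_max = 105, step = 1,
                          mode = "jittered", seed = 16)
  rec <- simulate_cohort(truth, plan)
  start <- truth
  start$slopes$f1 <- 0
  fit <- fit_time_dependent(rec, formulas = "f1", start = start,
                            fix = c("a", "b", "Q", "f", "mu0"))
  # with everything else held at truth the slope is well identified
  expect_equal(fit$params$slopes$f1, 0.1, tolerance = 0.5)
  expect_equal(fit$params$f1, 80, tolerance = 1.5)
})
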