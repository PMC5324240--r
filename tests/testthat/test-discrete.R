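test_that("the discrete hazard evaluates the quadratic form", {
  p <- discrete_params(u = 4, R = 0.95, Sigma = 5,
                       mu0 = 1e-5, b = 0, Q = 1e-6, theta = 0.1)
  expect_equal(discrete_hazard(p, 80, 0), 1e-5 + 1e-6 * 6400)
  expect_equal(discrete_hazard(p, 0, 0), 1e-5)
  expect_equal(discrete_hazard(p, 0, 10), 1e-5 * exp(1))
  expect_error(discrete_hazard(p, c(1, 2), 0), "length")
})

noiseless_pairs <- function(u, R, y0s, nstep = 6) {
  k <- length(u)
  rows <- list()
  for (s in seq_along(y0s)) {
    y <- y0s[[s]]
    for (j in seq_len(nstep)) {
      y2 <- drop(u + R %*% y)
      rows[[length(rows) + 1L]] <- data.frame(
        id = s, case = 0, t1 = 30 + j - 1, t2 = 30 + j,
        as.list(stats::setNames(y, paste0("V", 1:k))),
        as.list(stats::setNames(y2, paste0("V", 1:k, ".next"))))
      y <- y2
    }
  }
  paired_observations(do.call(rbind, rows), covariate_names = paste0("V", 1:k))
}

test_that("autoregression recovers noiseless dynamics exactly", {
  ar <- fit_autoregression(noiseless_pairs(4, matrix(0.95), list(60, 80, 100)))
  expect_equal(ar$u, 4, tolerance = 1e-10)
  expect_equal(ar$R[1, 1], 0.95, tolerance = 1e-10)
  expect_lt(ar$Sigma, 1e-10)

  R2 <- matrix(c(0.95, 0.001, 0.001, 0.95), 2, 2)
  ar2 <- fit_autoregression(noiseless_pairs(c(5, 10), R2,
                                            list(c(60, 90), c(100, 150), c(80, 120))))
  expect_equal(ar2$u, c(5, 10), tolerance = 1e-8)
  expect_equal(ar2$R, R2, tolerance = 1e-8)

  # constant covariate: singular design named in the error
  bad <- noiseless_pairs(4, matrix(0.95), list(60, 80))
  bad$V1 <- 70
  bad$V1.next <- 70
  expect_error(fit_autoregression(bad), "V1")
})

test_that("hazard MLE reduces to the closed-form Bernoulli estimate when y is constant", {
  # y identically 0: the bracket is mu0 alone; with theta fixed at 0 the
  # MLE of the per-interval death probability is the event fraction
  set.seed(2)
  n <- 400
  death <- rbinom(n, 1, 0.3)
  pr <- paired_observations(data.frame(
    id = 1:n, case = death, t1 = 50, t2 = 51,
    V1 = 0, V1.next = ifelse(death == 1, NA, 0)))
  fit <- fit_discrete_hazard(pr, fix = list(b = 0, Q = 0, theta = 0))
  expect_equal(fit$mu0, -log(1 - mean(death)) / 1, tolerance = 1e-6)
})

test_that("hazard MLE matches a brute-force likelihood scan on a toy cohort", {
  # one covariate taking values 0 and 80 over three intervals; only mu0
  # and Q free, so the likelihood can be scanned on a grid
  df <- data.frame(
    id = rep(1:2000, each = 3),
    case = 0, t1 = rep(c(50, 51, 52), 2000), t2 = rep(c(51, 52, 53), 2000),
    V1 = rep(c(0, 80, 80), 2000))
  df$V1.next <- c(df$V1[-1], NA)
  set.seed(9)
  ptrue <- function(y) 1 - exp(-(0.01 + 5e-6 * y^2))
  df$case <- rbinom(nrow(df), 1, ptrue(df$V1))
  # terminal bookkeeping: treat every row independently (fresh ids)
  df$id <- seq_len(nrow(df))
  df$V1.next <- ifelse(df$case == 1, NA, df$V1.next)
  pr <- paired_observations(df)
  fit <- fit_discrete_hazard(pr, fix = list(b = 0, theta = 0))

  # independent oracle: the same Bernoulli likelihood written directly in
  # R, located by a coarse grid and refined locally
  nll_scan <- function(par) {
    mu <- pmax(par[1] + par[2] * pr$V1^2, 0)
    p <- pmin(pmax(1 - exp(-mu), 1e-12), 1 - 1e-12)
    -sum(ifelse(pr$case == 1, log(p), log(1 - p)))
  }
  grid <- expand.grid(mu0 = seq(1e-4, 0.05, length.out = 80),
                      Q = seq(1e-7, 2e-5, length.out = 80))
  v <- mapply(function(m, q) nll_scan(c(m, q)), grid$mu0, grid$Q)
  best <- as.numeric(grid[which.min(v), ])
  ref <- stats::optim(best, nll_scan,
                      control = list(reltol = 1e-14, maxit = 20000,
                                     parscale = best))
  expect_equal(fit$mu0, ref$par[1], tolerance = 1e-3)
  expect_equal(fit$Q[1, 1], ref$par[2], tolerance = 1e-2)
  expect_lt(abs(fit$nll - ref$value), 1e-4)
})

test_that("an all-censored cohort raises the no-events error", {
  pr <- paired_observations(data.frame(
    id = 1:5, case = 0, t1 = 50, t2 = 51, V1 = 70, V1.next = 71))
  expect_error(fit_discrete_hazard(pr), "no events")
})

test_that("fit_discrete returns consistent dual parameterizations", {
  set.seed(12)
  plan <- simulation_plan(800, t_start = 30, t_max = 105, seed = 12)
  rec <- simulate_cohort(continuous_to_discrete(design_1d()), plan)
  prep <- prepare_data(rec, interval = 1)
  fit <- fit_discrete(prep$fixed)
  expect_s3_class(fit$discrete, "discrete_params")
  expect_s3_class(fit$continuous, "continuous_params")
  # the two forms are the same model: round-trip is exact
  back <- continuous_to_discrete(fit$continuous)
  for (nm in c("u", "R", "Sigma", "b", "Q", "mu0", "theta"))
    expect_equal(back[[nm]], fit$discrete[[nm]], tolerance = 1e-10)
  # and the fitted hazard is the published quadratic-deviation form
  y <- 85
  expect_equal(discrete_hazard(fit$discrete, y, 50),
               (fit$continuous$mu0 +
                  (y - fit$continuous$f)^2 * fit$continuous$Q[1, 1]) *
                 exp(fit$continuous$theta * 50),
               tolerance = 1e-10)
})

test_that("degenerate inputs fail with sample-size errors", {
  pr <- paired_observations(data.frame(
    id = 1, case = 0, t1 = 30, t2 = 31, V1 = 80, V1.next = 81))
  expect_error(fit_autoregression(pr), "at least")
})
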