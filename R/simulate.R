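#' Define a cohort simulation plan
#'
#' @param n_subjects number of individuals.
#' @param t_start entry age (years), default 30.
#' @param t_max censoring age (years), default 105.
#' @param step nominal interval between observations (years), default 1.
#' @param mode `"fixed"` (constant intervals; the discrete observational
#'   plan) or `"jittered"` (`dt = step + unif(-0.1 step, 0.1 step)`; the
#'   arbitrary-interval plan of the continuous-time model).
#' @param sigma0 standard deviation(s) of the initial biomarker draw
#'   `Y(t_start) ~ N(f1(t_start), diag(sigma0^2))`, recycled to k; default 1.
#' @param max_obs optional cap on the number of observations per subject
#'   (subjects are censored after `max_obs` observations).
#' @param seed optional integer seed for reproducible cohorts.
#' @return list of class `simulation_plan`.
#' @export
simulation_plan <- function(n_subjects, t_start = 30, t_max = 105, step = 1,
                            mode = c("fixed", "jittered"), sigma0 = 1,
                            max_obs = NULL, seed = NULL) {
  mode <- match.arg(mode)
  if (t_max <= t_start) stop("argument error: t_max must exceed t_start")
  if (step <= 0) stop("argument error: step must be positive")
  if (n_subjects < 1) stop("argument error: n_subjects must be >= 1")
  structure(list(n_subjects = as.integer(n_subjects), t_start = t_start,
                 t_max = t_max, step = step, mode = mode, sigma0 = sigma0,
                 max_obs = if (is.null(max_obs)) NULL else as.integer(max_obs),
                 seed = seed),
            class = "simulation_plan")
}

clamp0 <- function(x) pmax(x, 0)

#' Simulate a cohort under a stochastic process model
#'
#' Per subject: draw `Y(t_start) ~ N(mean0, diag(sigma0^2))` (by default
#' `mean0 = f1(t_start)`); then per observation interval compute the
#' conditional survival probability `S = exp(-integral of mu)`, draw
#' `r ~ U(0,1)`, record a death at the interval end when `r > S`, and
#' otherwise advance the biomarker — one autoregressive step for
#' discrete-time parameters, Euler-Maruyama with internal substep
#' `h = 0.01` years for continuous-time parameters (the hazard integral is
#' accumulated on the same substeps by the trapezoid rule). Subjects are
#' censored at `t_max` or after `max_obs` observations. Negative trial
#' hazards are clamped at zero for the probability computation. The random
#' number stream is fixed as: all initial draws, then per interval the
#' survival uniforms followed by the dynamics noise, so a given plan and
#' seed reproduce the cohort exactly.
#'
#' @param params a [discrete_params()] (fixed intervals only) or
#'   [continuous_params()] object.
#' @param plan a [simulation_plan()].
#' @param mean0 optional initial mean override (k-vector); defaults to the
#'   long-term mean `f1(t_start)` (for discrete parameters, the implied
#'   `f1 = -(R - I)^{-1} u`).
#' @return a [longitudinal_records()] object; covariates are named
#'   `V1 ... Vk`.
#' @export
simulate_cohort <- function(params, plan, mean0 = NULL) {
  stopifnot(inherits(plan, "simulation_plan"))
  if (!is.null(plan$seed)) set.seed(plan$seed)
  if (inherits(params, "discrete_params")) {
    if (plan$mode != "fixed")
      stop("argument error: the discrete-time model requires fixed intervals")
    simulate_discrete_cohort(params, plan, mean0)
  } else if (inherits(params, "continuous_params")) {
    simulate_continuous_cohort(params, plan, mean0)
  } else stop("argument error: params must be discrete_params or continuous_params")
}

sim_init <- function(k, n, mean0, sigma0) {
  s0 <- rep_len(sigma0, k)
  Y <- matrix(stats::rnorm(n * k, rep(mean0, each = n), rep(s0, each = n)), n, k)
  Y
}

emit_records <- function(rows, k) {
  df <- do.call(rbind, rows)
  df <- df[order(df$id, df$t1), , drop = FALSE]
  longitudinal_records(df, covariate_names = paste0("V", seq_len(k)))
}

simulate_discrete_cohort <- function(params, plan, mean0 = NULL) {
  k <- params$k
  n <- plan$n_subjects
  if (is.null(mean0)) {
    a <- params$R - diag(k)
    mean0 <- drop(-solve(a, params$u))
  }
  Y <- sim_init(k, n, mean0, plan$sigma0)
  dt <- plan$step
  alive <- rep(TRUE, n)
  nobs <- rep(0L, n)
  rows <- vector("list", 0L)
  t <- plan$t_start
  while (any(alive) && t + dt <= plan$t_max + 1e-9) {
    idx <- which(alive)
    mu <- clamp0(params$mu0 + drop(Y[idx, , drop = FALSE] %*% params$b) +
                   rowSums((Y[idx, , drop = FALSE] %*% params$Q) *
                             Y[idx, , drop = FALSE])) * exp(params$theta * t)
    S <- exp(-mu * dt)
    r <- stats::runif(length(idx))
    died <- r > S
    rows[[length(rows) + 1L]] <- sim_rows(idx, died, t, t + dt, Y[idx, , drop = FALSE], k)
    if (any(!is.finite(Y[idx, ])))
      stop(sprintf("simulation error: non-finite trajectory (subject %d, t = %.2f)",
                   idx[which(!is.finite(rowSums(Y[idx, , drop = FALSE])))[1]], t))
    surv <- idx[!died]
    eps <- matrix(stats::rnorm(length(idx) * k, 0, rep(params$Sigma, each = length(idx))),
                  length(idx), k)
    Ynew <- sweep(Y[idx, , drop = FALSE] %*% t(params$R), 2, params$u, "+") + eps
    Y[idx, ] <- Ynew
    alive[idx[died]] <- FALSE
    nobs[idx] <- nobs[idx] + 1L
    if (!is.null(plan$max_obs)) alive[nobs >= plan$max_obs] <- FALSE
    t <- t + dt
  }
  emit_records(rows, k)
}

sim_rows <- function(idx, died, t1, t2, Y1, k) {
  df <- data.frame(id = idx, event = as.integer(died), t1 = t1, t2 = t2)
  for (j in seq_len(k)) df[[paste0("V", j)]] <- Y1[, j]
  df
}

# hazard mu(t, Y) evaluated rowwise (vectorized over possibly distinct
# per-row times), clamped at zero
hazard_rows <- function(params, tv, Ym) {
  s <- params$slopes
  if (params$k == 1L) {
    y <- Ym[, 1]
    m0 <- pmax(params$mu0 + s$mu0 * tv, 0)
    qq <- pmax(params$Q[1, 1] + as.numeric(s$Q)[1] * tv, 0)
    d <- y - (params$f + s$f * tv)
    mu <- m0 + qq * d * d
  } else {
    d <- sweep(Ym, 2, params$f)
    mu <- clamp0(params$mu0 + rowSums((d %*% params$Q) * d))
  }
  if (params$exp_theta) mu <- mu * exp(params$theta * tv)
  mu
}

# one Euler-Maruyama drift evaluation, vectorized over rows
drift_rows <- function(params, tv, Ym) {
  s <- params$slopes
  if (params$k == 1L) {
    at <- params$a[1, 1] + as.numeric(s$a)[1] * tv
    f1t <- params$f1 + s$f1 * tv
    matrix(at * (Ym[, 1] - f1t), ncol = 1L)
  } else {
    sweep(Ym, 2, params$f1) %*% t(params$a)
  }
}

diffusion_rows <- function(params, tv, nrow_, k) {
  s <- params$slopes
  if (k == 1L) matrix(params$b + s$b * tv, ncol = 1L)
  else matrix(rep(params$b, each = nrow_), nrow_, k)
}

simulate_continuous_cohort <- function(params, plan, mean0 = NULL) {
  k <- params$k
  n <- plan$n_subjects
  if (is.null(mean0)) mean0 <- coefficients_at(params, plan$t_start)$f1
  Y <- sim_init(k, n, mean0, plan$sigma0)
  h <- 0.01
  alive <- rep(TRUE, n)
  nobs <- rep(0L, n)
  tcur <- rep(plan$t_start, n)
  rows <- vector("list", 0L)
  repeat {
    idx <- which(alive)
    if (!length(idx)) break
    dt <- if (plan$mode == "jittered")
      plan$step + stats::runif(length(idx), -0.1 * plan$step, 0.1 * plan$step)
    else rep(plan$step, length(idx))
    tend <- tcur[idx] + dt
    ok <- tend <= plan$t_max + 1e-9
    alive[idx[!ok]] <- FALSE  # would pass t_max: censored at current age
    if (!any(ok)) break
    idx <- idx[ok]; dt <- dt[ok]; tend <- tend[ok]
    r <- stats::runif(length(idx))

    Yi <- Y[idx, , drop = FALSE]
    t1i <- tcur[idx]
    # Euler-Maruyama with substep h; hazard integral accumulated on the
    # same substeps by the trapezoid rule; subjects may have distinct dt
    # (jittered plan), so each walks to its own endpoint
    nsub <- pmax(1L, ceiling(dt / h - 1e-9))
    maxsub <- max(nsub)
    hi <- dt / nsub
    Hint <- numeric(length(idx))
    tv <- t1i
    muprev <- hazard_rows(params, tv, Yi)
    for (s in seq_len(maxsub)) {
      act <- which(s <= nsub)
      if (!length(act)) break
      na <- length(act)
      Z <- matrix(stats::rnorm(na * k), na, k)
      Ya <- Yi[act, , drop = FALSE]
      ta <- tv[act]; ha <- hi[act]
      Ya <- Ya + drift_rows(params, ta, Ya) * ha +
        diffusion_rows(params, ta, na, k) * Z * sqrt(ha)
      Yi[act, ] <- Ya
      tv[act] <- ta + ha
      munew <- hazard_rows(params, tv[act], Ya)
      Hint[act] <- Hint[act] + 0.5 * (muprev[act] + munew) * ha
      muprev[act] <- munew
    }
    if (any(!is.finite(Yi)))
      stop(sprintf("simulation error: non-finite trajectory (subject %d, t = %.2f)",
                   idx[which(!is.finite(rowSums(Yi)))[1]], t1i[1]))
    died <- r > exp(-Hint)
    rows[[length(rows) + 1L]] <- sim_rows(idx, died, t1i, tend, Y[idx, , drop = FALSE], k)
    Y[idx, ] <- Yi
    tcur[idx] <- tend
    nobs[idx] <- nobs[idx] + 1L
    alive[idx[died]] <- FALSE
    if (!is.null(plan$max_obs)) alive[nobs >= plan$max_obs] <- FALSE
  }
  emit_records(rows, k)
}

#' Kaplan-Meier estimate with a Greenwood confidence band
#'
#' Product-limit estimator with Greenwood variance and a log-transformed
#' 95% confidence band (via `survival::survfit`).
#'
#' @param times positive event/censoring times.
#' @param events binary event indicators (1 = death).
#' @return data frame with `time, n_risk, surv, lower, upper`.
#' @export
kaplan_meier <- function(times, events) {
  if (!length(times)) stop("argument error: empty input")
  stopifnot(length(times) == length(events), all(times > 0),
            all(events %in% c(0, 1)))
  sf <- survival::survfit(survival::Surv(times, events) ~ 1,
                          conf.type = "log", conf.int = 0.95)
  data.frame(time = sf$time, n_risk = sf$n.risk, surv = sf$surv,
             lower = ifelse(is.na(sf$lower), 0, sf$lower),
             upper = ifelse(is.na(sf$upper), 1, sf$upper))
}

#' Simulate and summarize a projected cohort
#'
#' Runs [simulate_cohort()] with initial biomarkers drawn from
#' `N(initial_mean, diag(initial_sd^2))`, then summarizes the cohort with
#' the Kaplan-Meier survival curve (Greenwood band) and age-binned
#' biomarker means among survivors (bin width = `plan$step`).
#'
#' @param params model parameters (either form).
#' @param plan a [simulation_plan()].
#' @param initial_mean k-vector of initial biomarker means.
#' @param initial_sd k-vector of initial standard deviations (defaults to
#'   `plan$sigma0`).
#' @return list with `records` (the cohort) and `summary`, a list holding
#'   `survival` (Kaplan-Meier table) and `mean_by_age` (per-bin covariate
#'   means and at-risk counts).
#' @export
project <- function(params, plan, initial_mean, initial_sd = NULL) {
  if (!is.null(initial_sd)) plan$sigma0 <- initial_sd
  records <- simulate_cohort(params, plan, mean0 = initial_mean)
  covs <- attr(records, "covariates")
  df <- as.data.frame(records)
  last <- !duplicated(df$id, fromLast = TRUE)
  km <- kaplan_meier(df$t2[last], df$event[last])
  bins <- floor((df$t1 - plan$t_start) / plan$step + 1e-9)
  age <- plan$t_start + bins * plan$step
  agg <- stats::aggregate(df[, covs, drop = FALSE], by = list(age = age), FUN = mean)
  cnt <- as.data.frame(table(age = age), stringsAsFactors = FALSE)
  agg$n_at_risk <- cnt$Freq[match(as.character(agg$age), cnt$age)]
  list(records = records,
       summary = list(survival = km, mean_by_age = agg))
}
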