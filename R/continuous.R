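#' Evaluate the model coefficients at an age
#'
#' Applies the linear time dependence `base + slope * t` of each
#' coefficient and, when `exp_theta` is set, the `exp(theta t)` factor on
#' `mu0` and `Q`. Baseline hazard (and, for one-dimensional models, `Q`)
#' are clamped at zero.
#'
#' @param params a [continuous_params()] object.
#' @param t age (years).
#' @return list with elements `a, f1, b, Q, f, mu0` evaluated at `t`.
#' @export
coefficients_at <- function(params, t) {
  s <- params$slopes
  a <- params$a + s$a * t
  f1 <- params$f1 + s$f1 * t
  b <- params$b + s$b * t
  Q <- params$Q + s$Q * t
  f <- params$f + s$f * t
  mu0 <- params$mu0 + s$mu0 * t
  if (params$exp_theta) {
    e <- exp(params$theta * t)
    mu0 <- mu0 * e
    Q <- Q * e
  }
  if (mu0 < 0) mu0 <- 0
  if (params$k == 1L && Q[1, 1] < 0) Q[1, 1] <- 0
  list(a = a, f1 = f1, b = b, Q = Q, f = f, mu0 = mu0)
}

#' Initialize a moment state
#'
#' @param m conditional mean (k-vector).
#' @param gamma conditional covariance (k x k, symmetrized).
#' @param H accumulated integral of the marginal hazard.
#' @return list of class `moment_state`.
#' @export
moment_state <- function(m, gamma = matrix(0, length(m), length(m)), H = 0) {
  m <- as.numeric(m)
  k <- length(m)
  gamma <- as_square_matrix(gamma, k, "gamma")
  structure(list(m = m, gamma = (gamma + t(gamma)) / 2, H = as.numeric(H)),
            class = "moment_state")
}

#' Marginal hazard among survivors
#'
#' `mu0(t) + (m - f(t))' Q(t) (m - f(t)) + Tr(Q(t) gamma)`: the hazard
#' averaged over the conditional Gaussian distribution of the biomarker
#' among survivors.
#'
#' @param params a [continuous_params()] object.
#' @param state a [moment_state()].
#' @param t age (years).
#' @return hazard rate.
#' @export
marginal_hazard <- function(params, state, t) {
  if (length(state$m) != params$k)
    stop("argument error: state dimension does not match params")
  cf <- coefficients_at(params, t)
  d <- state$m - cf$f
  drop(cf$mu0 + d %*% cf$Q %*% d + sum(diag(cf$Q %*% state$gamma)))
}

moment_deriv <- function(params, t, m, gamma) {
  cf <- coefficients_at(params, t)
  GQ <- gamma %*% cf$Q
  dm <- drop(cf$a %*% (m - cf$f1)) - 2 * drop(GQ %*% (m - cf$f))
  dG <- cf$a %*% gamma + gamma %*% t(cf$a) + tcrossprod(cf$b) - 2 * GQ %*% gamma
  d <- m - cf$f
  dH <- drop(cf$mu0 + d %*% cf$Q %*% d + sum(diag(GQ)))
  list(dm = dm, dG = dG, dH = dH)
}

#' Propagate the conditional moments between observation times
#'
#' Integrates the moment equations
#' `dm/dt = a(t)(m - f1(t)) - 2 gamma Q(t) (m - f(t))` and
#' `dgamma/dt = a(t) gamma + gamma a(t)' + b(t) b(t)' - 2 gamma Q(t) gamma`
#' together with the accumulated marginal hazard `dH/dt = mubar(t)` by
#' classical 4th-order Runge-Kutta with fixed substep
#' `h = min(hmax, (t1 - t0)/4)`, returning the left limit of the state at
#' `t1`.
#'
#' @param params a [continuous_params()] object.
#' @param state a [moment_state()] at `t0`.
#' @param t0,t1 span endpoints, `t1 > t0`.
#' @param hmax maximum substep (years), default 0.05.
#' @return the [moment_state()] at `t1`.
#' @export
propagate_moments <- function(params, state, t0, t1, hmax = 0.05) {
  stopifnot(inherits(params, "continuous_params"), t1 > t0)
  n <- max(4L, ceiling((t1 - t0) / hmax))
  h <- (t1 - t0) / n
  m <- state$m; G <- state$gamma; H <- state$H
  for (s in seq_len(n)) {
    t <- t0 + (s - 1) * h
    k1 <- moment_deriv(params, t, m, G)
    k2 <- moment_deriv(params, t + h / 2, m + h / 2 * k1$dm, G + h / 2 * k1$dG)
    k3 <- moment_deriv(params, t + h / 2, m + h / 2 * k2$dm, G + h / 2 * k2$dG)
    k4 <- moment_deriv(params, t + h, m + h * k3$dm, G + h * k3$dG)
    m <- m + h / 6 * (k1$dm + 2 * k2$dm + 2 * k3$dm + k4$dm)
    G <- G + h / 6 * (k1$dG + 2 * k2$dG + 2 * k3$dG + k4$dG)
    H <- H + h / 6 * (k1$dH + 2 * k2$dH + 2 * k3$dH + k4$dH)
    G <- (G + t(G)) / 2
    if (any(!is.finite(m)) || any(!is.finite(G)) || !is.finite(H))
      stop(sprintf("numerical-blowup error: moment integration failed near t = %.4f", t))
  }
  moment_state(m, G, H)
}

#' Log-likelihood contribution of a single subject
#'
#' Reference (plain R) implementation of the continuous-time SPM
#' likelihood for one subject: Gaussian terms for every observation after
#' the first under the propagated conditional law (with reset `m := y`,
#' `gamma := 0` after each exact observation), the population-law density
#' of the first observation, and the survival/event term
#' `delta * log(mubar(tau)) - integral of mubar`.
#'
#' @param params a [continuous_params()] object.
#' @param records a [longitudinal_records()] object containing exactly one
#'   subject.
#' @param init_mean,init_cov population initial law of the first
#'   observation; set `init_mean = NULL` to omit the first-observation
#'   density term.
#' @param hmax RK4 substep bound.
#' @return scalar log-likelihood contribution.
#' @export
subject_log_likelihood <- function(params, records, init_mean = NULL,
                                   init_cov = NULL, hmax = 0.05) {
  df <- as.data.frame(records)
  covs <- attr(records, "covariates") %||% setdiff(names(df), c("id", "event", "t1", "t2"))
  if (length(unique(df$id)) != 1L)
    stop("argument error: records must contain exactly one subject")
  df <- df[order(df$t1), , drop = FALSE]
  tms <- df$t1
  if (any(diff(tms) <= 0)) stop("validation error: observation times must be strictly increasing")
  tau <- df$t2[nrow(df)]
  if (tau < tms[length(tms)]) stop("validation error: tau precedes the last observation")
  delta <- df$event[nrow(df)]
  Y <- as.matrix(df[, covs, drop = FALSE])
  k <- params$k
  ll <- 0
  if (!is.null(init_mean)) {
    r <- Y[1, ] - init_mean
    ic <- as_square_matrix(init_cov, k, "init_cov")
    ll <- ll - 0.5 * (k * log(2 * pi) + determinant(ic)$modulus[1] +
                        drop(r %*% solve(ic, r)))
  }
  st <- moment_state(Y[1, ])
  n <- nrow(df)
  if (n > 1L) for (j in 2:n) {
    st <- propagate_moments(params, st, tms[j - 1], tms[j], hmax = hmax)
    ld <- determinant(st$gamma)
    if (ld$sign <= 0) stop("singular-covariance error: |gamma(t-)| <= 0")
    r <- Y[j, ] - st$m
    ll <- ll - 0.5 * (k * log(2 * pi) + ld$modulus[1] +
                        drop(r %*% solve(st$gamma, r)))
    st <- moment_state(Y[j, ], H = st$H)
  }
  if (tau > tms[n]) st <- propagate_moments(params, st, tms[n], tau, hmax = hmax)
  if (delta == 1) {
    mb <- marginal_hazard(params, st, tau)
    if (mb <= 0) return(-Inf)
    ll <- ll + log(mb)
  }
  ll - st$H
}

# Flatten longitudinal records into the CSR-style arrays consumed by the
# compiled likelihood. Rows with any missing biomarker are dropped.
flatten_records <- function(records) {
  covs <- attr(records, "covariates")
  df <- as.data.frame(records)
  Y <- as.matrix(df[, covs, drop = FALSE])
  keep <- stats::complete.cases(Y)
  df <- df[keep, , drop = FALSE]
  Y <- Y[keep, , drop = FALSE]
  if (!nrow(df)) stop("estimation error: no complete observations")
  ids <- df$id
  ord <- order(ids, df$t1)
  df <- df[ord, , drop = FALSE]; Y <- Y[ord, , drop = FALSE]
  sp <- split(seq_len(nrow(df)), df$id)
  ptr <- c(0L, cumsum(vapply(sp, length, integer(1))))
  idx <- unlist(sp, use.names = FALSE)
  tau <- vapply(sp, function(i) df$t2[i[length(i)]], numeric(1))
  delta <- vapply(sp, function(i) df$event[i[length(i)]], numeric(1))
  first <- vapply(sp, function(i) i[1], integer(1))
  list(t_obs = df$t1[idx], Y = Y[idx, , drop = FALSE],
       ptr = as.integer(ptr), tau = as.numeric(tau),
       delta = as.numeric(delta),
       init_mean = colMeans(Y[first, , drop = FALSE]),
       init_cov = stats::cov(Y[first, , drop = FALSE]),
       k = length(covs), n_subjects = length(sp))
}

records_from_pairs <- function(pairs) {
  covs <- attr(pairs, "covariates")
  df <- as.data.frame(pairs)
  sp <- split(df, df$id)
  rows <- lapply(sp, function(s) {
    s <- s[order(s$t1), , drop = FALSE]
    out <- s[, c("id", "case", "t1", "t2", covs), drop = FALSE]
    names(out)[2] <- "event"
    out$event <- c(rep(0, nrow(s) - 1L), s$case[nrow(s)])
    out
  })
  longitudinal_records(do.call(rbind, rows), covariate_names = covs)
}

cont_loglik_cpp <- function(params, flat, include_first = TRUE, hmax = 0.05) {
  k <- params$k
  s <- params$slopes
  slmat <- function(x) {
    if (is.matrix(x)) return(as_square_matrix(x, k, "slope"))
    if (length(x) == 1L && k == 1L) return(matrix(as.numeric(x), 1L, 1L))
    matrix(0, k, k)
  }
  slvec <- function(x) {
    if (length(x) == k) return(as.numeric(x))
    rep(0, k)
  }
  cpp_continuous_loglik(flat$t_obs, flat$Y, flat$ptr, flat$tau, flat$delta,
                        params$a, slmat(s$a),
                        params$f1, slvec(s$f1),
                        params$b, slvec(s$b),
                        params$Q, slmat(s$Q),
                        params$f, slvec(s$f),
                        params$mu0, as.numeric(s$mu0), params$theta,
                        params$exp_theta,
                        flat$init_mean,
                        as_square_matrix(flat$init_cov, k, "init_cov"),
                        include_first, hmax)
}

#' Total log-likelihood of the continuous-time SPM over a cohort
#'
#' Evaluates the moment-ODE likelihood (compiled RK4 core) for a set of
#' longitudinal records. The population initial law used for the
#' first-observation density is the sample mean and covariance of the
#' subjects' first observations unless supplied.
#'
#' @param params a [continuous_params()] object.
#' @param records a [longitudinal_records()] object (or paired table, which
#'   is reassembled into records).
#' @param init_mean,init_cov optional population initial law override.
#' @param include_first include the first-observation density term?
#' @param hmax RK4 substep bound (years).
#' @return scalar log-likelihood.
#' @export
spm_log_likelihood <- function(params, records, init_mean = NULL,
                               init_cov = NULL, include_first = TRUE,
                               hmax = 0.05) {
  if (inherits(records, "paired_observations")) records <- records_from_pairs(records)
  flat <- flatten_records(records)
  if (flat$k != params$k) stop("argument error: dimension mismatch between params and data")
  if (!is.null(init_mean)) flat$init_mean <- as.numeric(init_mean)
  if (!is.null(init_cov)) flat$init_cov <- init_cov
  if (any(!is.finite(flat$init_cov))) {
    flat$init_cov <- diag(1, params$k)   # single-subject corner case
  }
  cont_loglik_cpp(params, flat, include_first = include_first, hmax = hmax)
}

# ---------------------------------------------------------------------------
# fitting

# Build pack/unpack between an unconstrained optimizer vector and a
# continuous_params object. Positivity of mu0 via log, PSD of Q via a
# Cholesky factor. `td` names coefficients with a free linear slope
# (k = 1 only); `fix` names coefficients held at their start value.
cont_parameterization <- function(start, td = character(0), fix = character(0)) {
  k <- start$k
  nL <- k * (k + 1L) / 2L
  Ls <- t(chol(start$Q + diag(1e-12 * max(diag(start$Q)) + 1e-300, k)))
  blocks <- list(
    a = list(len = k * k, get = function(p) as.numeric(p$a),
             set = function(p, v) { p$a <- matrix(v, k, k); p }),
    f1 = list(len = k, get = function(p) p$f1,
              set = function(p, v) { p$f1 <- v; p }),
    b = list(len = k, get = function(p) p$b,
             set = function(p, v) { p$b <- v; p }),
    Q = list(len = nL, get = function(p) vech(t(chol(p$Q))),
             set = function(p, v) { L <- unvech_lower(v, k); p$Q <- L %*% t(L); p }),
    f = list(len = k, get = function(p) p$f,
             set = function(p, v) { p$f <- v; p }),
    mu0 = list(len = 1L, get = function(p) log(max(p$mu0, 1e-300)),
               set = function(p, v) { p$mu0 <- exp(v); p }),
    theta = list(len = 1L, get = function(p) p$theta,
                 set = function(p, v) { p$theta <- v; p }))
  est <- setdiff(names(blocks), fix)
  if (!start$exp_theta) est <- setdiff(est, "theta")
  sl_est <- td
  pack <- function(p) {
    v <- unlist(lapply(est, function(nm) blocks[[nm]]$get(p)), use.names = FALSE)
    c(v, vapply(sl_est, function(nm) as.numeric(p$slopes[[nm]]), numeric(1)))
  }
  unpack <- function(par, proto) {
    par <- unname(par)
    i <- 0L
    p <- proto
    for (nm in est) {
      len <- blocks[[nm]]$len
      p <- blocks[[nm]]$set(p, par[i + seq_len(len)])
      i <- i + len
    }
    for (nm in sl_est) {
      i <- i + 1L
      p$slopes[[nm]] <- par[i]
    }
    p$Q <- (p$Q + t(p$Q)) / 2
    p
  }
  # parscale: base coordinates scale with their start magnitude; slope
  # coordinates (which start at zero) scale with base magnitude per 50
  # years of follow-up
  scale_of <- function(p) {
    base <- unlist(lapply(est, function(nm) blocks[[nm]]$get(p)), use.names = FALSE)
    slsc <- vapply(sl_est, function(nm) {
      b <- if (nm == "mu0") p$mu0 else mean(abs(p[[nm]]))
      max(abs(b), 1e-3) / 50
    }, numeric(1))
    c(pmax(abs(base), 1e-3), slsc)
  }
  list(pack = pack, unpack = unpack, scale_of = scale_of,
       est = est, slopes = sl_est)
}

unvech_lower <- function(v, k) {
  L <- matrix(0, k, k)
  L[lower.tri(L, diag = TRUE)] <- v
  L
}

nm_maximize <- function(fn, par0, scale0 = NULL, maxit = 3000L,
                        reltol = 1e-8, restarts = 1L) {
  scale <- scale0 %||% pmax(abs(par0), 1e-3)
  opt <- stats::optim(par0, fn, method = "Nelder-Mead",
                      control = list(maxit = maxit, reltol = reltol,
                                     parscale = scale, fnscale = -1))
  for (r in seq_len(restarts)) {
    scale <- pmax(abs(opt$par), 0.1 * scale)
    o2 <- stats::optim(opt$par, fn, method = "Nelder-Mead",
                       control = list(maxit = maxit, reltol = reltol,
                                      parscale = scale, fnscale = -1))
    if (o2$value >= opt$value) opt <- o2
  }
  opt
}

default_continuous_start <- function(records, interval = 1) {
  prep <- prepare_data(records, interval = interval, impute = TRUE)
  fit <- fit_discrete(prep$fixed)
  if (is.null(fit$continuous))
    stop("start-value error: discrete-model start could not be converted")
  fit$continuous
}

#' Fit the continuous-time SPM by maximum likelihood
#'
#' Maximizes the moment-ODE likelihood over `a, f1, b, Q, f, mu0` (plus
#' `theta` when `use_exp_theta`) by Nelder-Mead. Positivity of `mu0` and
#' positive semi-definiteness of `Q` are enforced by optimizing `log mu0`
#' and a Cholesky factor of `Q`. The default start is the discrete-time
#' fit converted to continuous form.
#'
#' @param records a [longitudinal_records()] object (or a paired table).
#' @param start a [continuous_params()] object, or `"from_discrete"`.
#' @param use_exp_theta multiply `mu0` and `Q` by `exp(theta t)` and
#'   estimate `theta`?
#' @param fix character vector of coefficient names to hold at their start
#'   values.
#' @param hmax RK4 substep bound.
#' @param maxit Nelder-Mead iteration cap per pass.
#' @param restarts number of Nelder-Mead restarts from the incumbent.
#' @return list with `params` (the fitted [continuous_params()]),
#'   `loglik`, `convergence` (0 = converged), `counts` and `start`.
#' @export
fit_continuous <- function(records, start = "from_discrete",
                           use_exp_theta = FALSE, fix = character(0),
                           hmax = 0.05, maxit = 3000L, restarts = 1L) {
  if (inherits(records, "paired_observations")) records <- records_from_pairs(records)
  if (identical(start, "from_discrete")) start <- default_continuous_start(records)
  stopifnot(inherits(start, "continuous_params"))
  start$exp_theta <- isTRUE(use_exp_theta)
  if (min(eigen(start$Q, symmetric = TRUE, only.values = TRUE)$values) <= 0)
    stop("start-value error: starting Q must be positive definite")
  if (start$mu0 <= 0) start$mu0 <- 1e-8
  flat <- flatten_records(records)
  if (flat$k != start$k) stop("argument error: dimension mismatch")
  if (sum(flat$delta) < 1) stop("estimation error: no events observed")
  pz <- cont_parameterization(start, fix = fix)
  par0 <- pz$pack(start)
  fn <- function(par) cont_loglik_cpp(pz$unpack(par, start), flat, hmax = hmax)
  opt <- nm_maximize(fn, par0, pz$scale_of(start), maxit = maxit,
                     restarts = restarts)
  fitted <- pz$unpack(opt$par, start)
  list(params = fitted, loglik = opt$value, convergence = opt$convergence,
       counts = opt$counts, start = start,
       init_mean = flat$init_mean, init_cov = flat$init_cov)
}

#' Fit the one-dimensional SPM with linearly time-dependent coefficients
#'
#' Same likelihood machinery as [fit_continuous()], with selected
#' coefficients evaluated as `base + slope * t` at every integration
#' substep. Slope start values are zero; base start values come from the
#' discrete-time model unless `start` is supplied. Only one-dimensional
#' models are supported.
#'
#' @param records a [longitudinal_records()] object with one biomarker.
#' @param formulas character vector naming the coefficients given a free
#'   linear slope, among `a, f1, b, Q, f, mu0` (e.g. `c("f1")`).
#' @param start `"from_discrete"` or a [continuous_params()] object.
#' @param fix character vector of base coefficients held at their start
#'   values (e.g. `"theta"` is not needed: `theta` is only estimated when
#'   `use_exp_theta`).
#' @param use_exp_theta estimate a Gompertz factor on `mu0` and `Q`?
#' @param hmax,maxit,restarts numerical controls as in [fit_continuous()].
#' @return list as in [fit_continuous()]; the fitted slopes are in
#'   `params$slopes`.
#' @export
fit_time_dependent <- function(records, formulas = c("f1"),
                               start = "from_discrete", fix = character(0),
                               use_exp_theta = FALSE,
                               hmax = 0.05, maxit = 4000L, restarts = 1L) {
  if (inherits(records, "paired_observations")) records <- records_from_pairs(records)
  if (n_covariates(records) != 1L)
    stop("unsupported-configuration error: time-dependent coefficients require exactly one covariate")
  ok_names <- c("a", "f1", "b", "Q", "f", "mu0")
  if (!all(formulas %in% ok_names))
    stop("unknown coefficient in 'formulas': ",
         paste(setdiff(formulas, ok_names), collapse = ", "))
  if (identical(start, "from_discrete")) start <- default_continuous_start(records)
  stopifnot(inherits(start, "continuous_params"), start$k == 1L)
  start$exp_theta <- isTRUE(use_exp_theta)
  if (start$mu0 <= 0) start$mu0 <- 1e-8
  if (start$Q[1, 1] <= 0) start$Q[1, 1] <- 1e-8
  for (nm in formulas) start$slopes[[nm]] <- 0  # paper rule: slopes start at 0
  flat <- flatten_records(records)
  if (sum(flat$delta) < 1) stop("estimation error: no events observed")
  pz <- cont_parameterization(start, td = formulas, fix = fix)
  par0 <- pz$pack(start)
  fn <- function(par) cont_loglik_cpp(pz$unpack(par, start), flat, hmax = hmax)
  opt <- nm_maximize(fn, par0, pz$scale_of(start), maxit = maxit,
                     restarts = restarts)
  fitted <- pz$unpack(opt$par, start)
  list(params = fitted, loglik = opt$value, convergence = opt$convergence,
       counts = opt$counts, start = start,
       init_mean = flat$init_mean, init_cov = flat$init_cov)
}
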