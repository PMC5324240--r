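#' Discrete-time SPM parameter set
#'
#' Bundles the coefficients of the discrete-time stochastic process model
#' \deqn{Y(t+1) = u + R Y(t) + \epsilon,\qquad
#'       \mu(t, Y) = [\mu_0 + b Y + Y^* Q Y]\,e^{\theta t}}
#' where `Y` is the k-vector of biomarker values, `u` the autoregression
#' intercept, `R` the k x k autoregression matrix, `Sigma` the residual
#' standard deviations of the autoregression, and `(mu0, b, Q, theta)` the
#' quadratic-hazard coefficients. `Q` is symmetrized on construction.
#'
#' @param u numeric k-vector, autoregression intercept.
#' @param R numeric k x k matrix, autoregression coefficient.
#' @param Sigma numeric k-vector of residual standard deviations (>= 0).
#' @param mu0 scalar baseline hazard.
#' @param b numeric k-vector, linear hazard term.
#' @param Q numeric k x k matrix, quadratic hazard term (symmetrized).
#' @param theta scalar log-rate of hazard growth with age.
#' @return an object of class `discrete_params`.
#' @export
discrete_params <- function(u, R, Sigma, mu0, b, Q, theta = 0) {
  u <- as.numeric(u)
  k <- length(u)
  R <- as_square_matrix(R, k, "R")
  Sigma <- as.numeric(Sigma)
  b <- as.numeric(b)
  Q <- as_square_matrix(Q, k, "Q")
  stopifnot(length(Sigma) == k, length(b) == k,
            length(mu0) == 1L, length(theta) == 1L)
  if (any(!is.finite(c(u, R, Sigma, mu0, b, Q, theta))))
    stop("discrete_params: all coefficients must be finite")
  if (any(Sigma < 0)) stop("discrete_params: Sigma must be non-negative")
  Q <- (Q + t(Q)) / 2
  structure(list(k = k, u = u, R = R, Sigma = Sigma,
                 mu0 = as.numeric(mu0), b = b, Q = Q,
                 theta = as.numeric(theta)),
            class = "discrete_params")
}

#' Continuous-time SPM parameter set
#'
#' Bundles the coefficients of the continuous-time stochastic process model
#' \deqn{dY(t) = a(t)\,(Y(t) - f_1(t))\,dt + b(t)\,dW(t)}
#' \deqn{\mu(t, Y) = \mu_0(t) + (Y - f(t))^* Q(t) (Y - f(t))}
#' `a` is the negative-feedback (adaptive-capacity) matrix, `f1` the
#' long-term mean (allostatic) trajectory, `b` the diffusion strength,
#' `f` the risk-minimizing physiological norm, `Q` the risk sensitivity and
#' `mu0` the baseline hazard. Each of `a, f1, b, Q, f, mu0` may carry a
#' linear time slope (one-dimensional models only), so that e.g.
#' `a(t) = a + slope_a * t`. When `exp_theta` is `TRUE`, `mu0(t)` and `Q(t)`
#' are additionally multiplied by `exp(theta * t)`.
#'
#' A warning (not an error) is issued when `a` has eigenvalues with
#' non-negative real part (non-mean-reverting dynamics) or when `Q` is not
#' positive semi-definite.
#'
#' @param a numeric k x k matrix, negative feedback coefficient.
#' @param f1 numeric k-vector, long-term mean trajectory at t = 0.
#' @param b numeric k-vector, diffusion strength.
#' @param Q numeric k x k matrix, quadratic risk sensitivity (symmetrized).
#' @param f numeric k-vector, risk-minimizing trajectory at t = 0.
#' @param mu0 scalar baseline hazard at t = 0.
#' @param theta scalar exponent used when `exp_theta = TRUE`.
#' @param exp_theta logical; multiply `mu0` and `Q` by `exp(theta * t)`?
#' @param slopes optional named list with any of `a, f1, b, Q, f, mu0`
#'   giving linear time slopes (k = 1 models only; defaults are all zero).
#' @return an object of class `continuous_params`.
#' @export
continuous_params <- function(a, f1, b, Q, f, mu0, theta = 0,
                              exp_theta = FALSE, slopes = list()) {
  f1 <- as.numeric(f1)
  k <- length(f1)
  a <- as_square_matrix(a, k, "a")
  b <- as.numeric(b)
  f <- as.numeric(f)
  Q <- as_square_matrix(Q, k, "Q")
  stopifnot(length(b) == k, length(f) == k,
            length(mu0) == 1L, length(theta) == 1L)
  if (any(!is.finite(c(a, f1, b, Q, f, mu0, theta))))
    stop("continuous_params: all coefficients must be finite")
  Q <- (Q + t(Q)) / 2
  sl <- list(a = 0, f1 = 0, b = 0, Q = 0, f = 0, mu0 = 0)
  if (length(slopes)) {
    bad <- setdiff(names(slopes), names(sl))
    if (length(bad)) stop("unknown slope name(s): ", paste(bad, collapse = ", "))
    if (k > 1L && any(vapply(slopes, function(x) any(x != 0), logical(1))))
      stop("time-dependent (slope) coefficients are supported only for k = 1")
    sl[names(slopes)] <- lapply(slopes, as.numeric)
  }
  if (any(Re(eigen(a, only.values = TRUE)$values) >= 0))
    warning("continuous_params: 'a' has eigenvalue(s) with non-negative real part; process is not mean-reverting")
  if (min(eigen(Q, symmetric = TRUE, only.values = TRUE)$values) < -1e-10)
    warning("continuous_params: 'Q' is not positive semi-definite")
  structure(list(k = k, a = a, f1 = f1, b = b, Q = Q, f = f,
                 mu0 = as.numeric(mu0), theta = as.numeric(theta),
                 exp_theta = isTRUE(exp_theta), slopes = sl),
            class = "continuous_params")
}

as_square_matrix <- function(x, k, name) {
  if (is.null(dim(x))) {
    if (length(x) == 1L && k == 1L) x <- matrix(x, 1L, 1L)
    else if (length(x) == k * k) x <- matrix(x, k, k)
    else stop(sprintf("'%s' must be a %d x %d matrix", name, k, k))
  }
  x <- as.matrix(x)
  if (!all(dim(x) == c(k, k)))
    stop(sprintf("'%s' must be a %d x %d matrix", name, k, k))
  storage.mode(x) <- "double"
  x
}

#' @export
print.discrete_params <- function(x, ...) {
  cat(sprintf("Discrete-time SPM parameters (k = %d)\n", x$k))
  cat("u:     ", signif(x$u, 6), "\n")
  cat("R:\n"); print(signif(x$R, 6))
  cat("Sigma: ", signif(x$Sigma, 6), "\n")
  cat("mu0:   ", signif(x$mu0, 6), "\n")
  cat("b:     ", signif(x$b, 6), "\n")
  cat("Q:\n"); print(signif(x$Q, 6))
  cat("theta: ", signif(x$theta, 6), "\n")
  invisible(x)
}

#' @export
print.continuous_params <- function(x, ...) {
  cat(sprintf("Continuous-time SPM parameters (k = %d)\n", x$k))
  cat("a:\n"); print(signif(x$a, 6))
  cat("f1:    ", signif(x$f1, 6), "\n")
  cat("b:     ", signif(x$b, 6), "\n")
  cat("Q:\n"); print(signif(x$Q, 6))
  cat("f:     ", signif(x$f, 6), "\n")
  cat("mu0:   ", signif(x$mu0, 6), "\n")
  cat("theta: ", signif(x$theta, 6),
      if (x$exp_theta) " (mu0, Q scaled by exp(theta t))" else "", "\n")
  td <- names(Filter(function(s) any(s != 0), x$slopes))
  if (length(td)) cat("time-dependent:", paste(td, collapse = ", "), "\n")
  invisible(x)
}

solve_checked <- function(M, name) {
  if (!is.finite(rc <- rcond(M)) || rc < 1e-14)
    stop(sprintf("conversion requires full-rank '%s' (matrix is singular to working precision)", name))
  solve(M)
}

#' Convert discrete-time SPM coefficients to continuous form
#'
#' Exact algebraic map between the two parameterizations, valid for a unit
#' observation interval:
#' `Q_c = Q_d`, `a = R - I`, `b_c = Sigma`, `f1 = -a^{-1} u`,
#' `f = -0.5 * b_d Q_d^{-1}`, `mu0_c = mu0_d - f' Q f`, `theta_c = theta_d`.
#' Requires `R - I` and `Q` to be full rank.
#'
#' @param d a [discrete_params()] object.
#' @param step observation interval the discrete model was fitted on; the
#'   map is only valid for equal unit intervals, so any value other than 1
#'   is refused.
#' @return a [continuous_params()] object.
#' @export
discrete_to_continuous <- function(d, step = 1) {
  stopifnot(inherits(d, "discrete_params"))
  if (abs(step - 1) > 1e-9)
    stop("coefficient conversion is defined for a unit observation interval; got step = ", step)
  a <- d$R - diag(d$k)
  ainv <- solve_checked(a, "R - I")
  Qinv <- solve_checked(d$Q, "Q")
  f1 <- drop(-ainv %*% d$u)
  f <- drop(-0.5 * (d$b %*% Qinv))  # b is a 1 x k row vector in the hazard
  mu0 <- d$mu0 - drop(f %*% d$Q %*% f)
  continuous_params(a = a, f1 = f1, b = d$Sigma, Q = d$Q, f = f,
                    mu0 = mu0, theta = d$theta)
}

#' Convert continuous-time SPM coefficients to discrete form
#'
#' Exact inverse of [discrete_to_continuous()]:
#' `R = a + I`, `u = -a f1`, `Sigma = b_c`, `b_d = -2 f' Q`,
#' `mu0_d = mu0_c + f' Q f`, `theta_d = theta_c`.
#'
#' @param p a [continuous_params()] object (constant coefficients only).
#' @param step observation interval; must be 1 (see [discrete_to_continuous()]).
#' @return a [discrete_params()] object.
#' @export
continuous_to_discrete <- function(p, step = 1) {
  stopifnot(inherits(p, "continuous_params"))
  if (abs(step - 1) > 1e-9)
    stop("coefficient conversion is defined for a unit observation interval; got step = ", step)
  if (any(vapply(p$slopes, function(s) any(s != 0), logical(1))))
    stop("conversion is defined for constant coefficients only")
  solve_checked(p$Q, "Q")  # required full-rank for the inverse map
  R <- p$a + diag(p$k)
  u <- drop(-p$a %*% p$f1)
  bd <- drop(-2 * (p$f %*% p$Q))
  mu0 <- p$mu0 + drop(p$f %*% p$Q %*% p$f)
  discrete_params(u = u, R = R, Sigma = p$b, mu0 = mu0, b = bd, Q = p$Q,
                  theta = p$theta)
}

#' Write a parameter set (both forms when available) to JSON
#'
#' @param params a `discrete_params` or `continuous_params` object, or a
#'   list with elements `discrete` and/or `continuous`.
#' @param path output file path.
#' @export
write_params_json <- function(params, path) {
  if (inherits(params, "discrete_params")) params <- list(discrete = params)
  if (inherits(params, "continuous_params")) params <- list(continuous = params)
  ser <- lapply(params, function(p) {
    if (inherits(p, c("discrete_params", "continuous_params")))
      unclass(p)
    else p
  })
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' Read a parameter set written by [write_params_json()]
#'
#' @param path JSON file path.
#' @return a list with `discrete` and/or `continuous` parameter objects.
#' @export
read_params_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- list()
  if (!is.null(raw$discrete)) {
    d <- raw$discrete
    out$discrete <- discrete_params(d$u, d$R, d$Sigma, d$mu0, d$b, d$Q, d$theta)
  }
  if (!is.null(raw$continuous)) {
    p <- raw$continuous
    slopes <- p$slopes
    if (!is.null(slopes)) slopes <- Filter(function(s) any(s != 0), slopes)
    out$continuous <- continuous_params(p$a, p$f1, p$b, p$Q, p$f, p$mu0,
                                        theta = p$theta %||% 0,
                                        exp_theta = isTRUE(p$exp_theta),
                                        slopes = slopes %||% list())
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
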