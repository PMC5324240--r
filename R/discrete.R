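#' Evaluate the discrete-time quadratic hazard
#'
#' Computes `[mu0 + b'y + y'Qy] * exp(theta * t)`. The value may be
#' negative for pathological coefficient sets; probability computations
#' clamp at zero, this function does not.
#'
#' @param params a [discrete_params()] object.
#' @param y numeric k-vector of biomarker values.
#' @param t age (years).
#' @return hazard rate per unit time.
#' @export
discrete_hazard <- function(params, y, t) {
  stopifnot(inherits(params, "discrete_params"))
  y <- as.numeric(y)
  if (length(y) != params$k)
    stop(sprintf("argument error: 'y' has length %d, expected %d", length(y), params$k))
  drop(params$mu0 + sum(params$b * y) + y %*% params$Q %*% y) *
    exp(params$theta * t)
}

#' Fit the autoregressive dynamics of the discrete-time SPM
#'
#' Ordinary least squares of `y2` on `[1, y1]` jointly across all rows of a
#' fixed-interval paired table: `Y(t+1) = u + R Y(t) + eps`. `Sigma` holds
#' the residual standard deviations per biomarker.
#'
#' @param pairs a `paired_observations` table (fixed-interval layout); rows
#'   without `y2` (terminal intervals) are ignored.
#' @return list with `u` (k-vector), `R` (k x k), `Sigma` (k-vector) and
#'   `n` (rows used).
#' @export
fit_autoregression <- function(pairs) {
  covs <- attr(pairs, "covariates")
  k <- length(covs)
  Y2 <- as.matrix(pairs[, paste0(covs, ".next"), drop = FALSE])
  Y1 <- as.matrix(pairs[, covs, drop = FALSE])
  ok <- stats::complete.cases(Y1, Y2)
  Y1 <- Y1[ok, , drop = FALSE]; Y2 <- Y2[ok, , drop = FALSE]
  n <- nrow(Y1)
  if (n < k + 2L)
    stop(sprintf("estimation error: need at least %d complete pairs, got %d", k + 2L, n))
  X <- cbind(1, Y1)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- setdiff(seq_len(ncol(X)), qrX$pivot[seq_len(qrX$rank)])
    culprit <- if (any(dropped > 1)) covs[dropped[dropped > 1][1] - 1L] else "(intercept)"
    stop(sprintf("rank-deficiency error: design is singular (covariate '%s')", culprit))
  }
  B <- qr.coef(qrX, Y2)            # (k+1) x k; column j models covariate j
  res <- Y2 - X %*% B
  sigma <- sqrt(colSums(res^2) / (n - (k + 1L)))
  list(u = unname(B[1, ]), R = unname(t(B[-1, , drop = FALSE])),
       Sigma = unname(sigma), n = n)
}

# symmetric-matrix packing used by the hazard optimizer
vech_index <- function(k) which(lower.tri(diag(k), diag = TRUE), arr.ind = TRUE)
vech <- function(M) M[lower.tri(M, diag = TRUE)]
unvech <- function(v, k) {
  M <- matrix(0, k, k)
  M[lower.tri(M, diag = TRUE)] <- v
  M + t(M) - diag(diag(M), k)
}

#' Fit the quadratic-hazard coefficients of the discrete-time SPM
#'
#' Maximizes the exact Bernoulli likelihood in which the probability of
#' death over an interval is `1 - exp(-mu(t1, y1) * dt)`, with
#' `mu(t, y) = [mu0 + b'y + y'Qy] exp(theta t)` evaluated at the interval
#' start. A log-link binomial GLM on `[1, y, pairwise products of y, t]`
#' supplies starting values; the reported estimate is the Nelder-Mead
#' maximum of the exact likelihood (internally run on a centred-age,
#' scaled-biomarker parameterization for conditioning, then mapped back).
#' Negative hazards during the search are handled by clamping the interval
#' death probability to `[1e-12, 1 - 1e-12]`.
#'
#' @param pairs a `paired_observations` table with event flags in `case`.
#' @param dt nominal interval width; only used as a fallback when a row's
#'   own `t2 - t1` is unavailable (per-row exposure is used by default).
#' @param fix optional named list fixing coefficients at given values
#'   instead of estimating them, e.g. `list(theta = 0)`; recognised names
#'   are `mu0`, `b`, `Q`, `theta`.
#' @param control list: `maxit` per Nelder-Mead pass, `reltol`, `restarts`.
#' @return list with `mu0`, `b`, `Q`, `theta`, the negative log-likelihood
#'   `nll`, `convergence` (0 = converged) and `n_events`.
#' @export
fit_discrete_hazard <- function(pairs, dt = NULL, fix = list(),
                                control = list()) {
  covs <- attr(pairs, "covariates")
  k <- length(covs)
  Y <- as.matrix(pairs[, covs, drop = FALSE])
  ok <- stats::complete.cases(Y)
  Y <- Y[ok, , drop = FALSE]
  case <- pairs$case[ok]
  t1 <- pairs$t1[ok]
  dts <- pairs$t2[ok] - pairs$t1[ok]
  if (!is.null(dt)) dts[!is.finite(dts)] <- dt
  if (sum(case) < 1) stop("estimation error: no events observed")
  # rows sorted by age so the compiled likelihood can reuse exp(theta t)
  ord <- order(t1)
  Y <- Y[ord, , drop = FALSE]; case <- case[ord]; t1 <- t1[ord]; dts <- dts[ord]

  ctrl <- utils::modifyList(list(maxit = 1500L, reltol = 1e-7, restarts = 1L),
                            control)

  tbar <- mean(t1)
  sy <- apply(Y, 2, stats::sd); sy[!is.finite(sy) | sy == 0] <- 1
  Z <- sweep(Y, 2, sy, "/")

  # --- starting values: log-link binomial GLM on [1, y, products, t] -----
  start <- hazard_start_values(Z, case, t1 - tbar, dts, k)
  # internal parameterization: (mu0*, b*, vech Q*, theta) on centred age,
  # scaled biomarkers; mu0* = mu0 e^{theta tbar}, b*_i = b_i s_i e^{theta tbar},
  # Q*_ij = Q_ij s_i s_j e^{theta tbar}
  free <- c(mu0 = !("mu0" %in% names(fix)),
            b = !("b" %in% names(fix)),
            Q = !("Q" %in% names(fix)),
            theta = !("theta" %in% names(fix)))
  fixv <- list(
    mu0 = if (!free["mu0"]) as.numeric(fix$mu0) else NA_real_,
    b = if (!free["b"]) rep_len(as.numeric(fix$b), k) else rep(NA_real_, k),
    Q = if (!free["Q"]) as_square_matrix(rep_len(as.numeric(fix$Q), k * k), k, "Q") else NULL,
    theta = if (!free["theta"]) as.numeric(fix$theta) else NA_real_)

  pack <- function(mu0s, bs, Qs, th) {
    out <- numeric(0)
    if (free["mu0"]) out <- c(out, mu0s)
    if (free["b"]) out <- c(out, bs)
    if (free["Q"]) out <- c(out, vech(Qs))
    if (free["theta"]) out <- c(out, th)
    out
  }
  unpack <- function(par) {
    i <- 0L
    th <- if (free["theta"]) par[length(par)] else fixv$theta
    sc <- exp(th * tbar)
    if (free["mu0"]) { i <- i + 1L; mu0s <- par[i] } else mu0s <- fixv$mu0 * sc
    if (free["b"]) { bs <- par[i + seq_len(k)]; i <- i + k }
    else bs <- fixv$b * sy * sc
    if (free["Q"]) {
      v <- par[i + seq_len(k * (k + 1L) / 2L)]; i <- i + length(v)
      Qs <- unvech(v, k)
    } else Qs <- fixv$Q * tcrossprod(sy) * sc
    list(mu0s = mu0s, bs = bs, Qs = Qs, theta = th)
  }

  th0 <- if (free["theta"]) start$theta else fixv$theta
  sc0 <- exp(th0 * tbar)
  par0 <- pack(if (free["mu0"]) start$mu0s else NULL,
               if (free["b"]) start$bs else NULL,
               if (free["Q"]) start$Qs else NULL,
               if (free["theta"]) start$theta else NULL)
  if (!length(par0)) stop("argument error: no free coefficients to estimate")

  tc <- t1 - tbar
  nq <- k * (k + 1L) / 2L
  nll <- function(par) {
    p <- unpack(par)
    cpp_discrete_nll(p$mu0s, p$bs, p$Qs, p$theta, Z, tc, dts, case)
  }
  # analytic gradient on the internal parameterization; fixed blocks feed
  # theta through their exp(theta tbar) factor (chain term)
  nll_grad <- function(par) {
    p <- unpack(par)
    g <- cpp_discrete_nll_grad(p$mu0s, p$bs, p$Qs, p$theta, Z, tc, dts, case)
    gm <- g[1]; gb <- g[1 + seq_len(k)]; gq <- g[1 + k + seq_len(nq)]
    gth <- g[2 + k + nq]
    out <- numeric(0)
    if (free["mu0"]) out <- c(out, gm) else gth <- gth + gm * p$mu0s * tbar
    if (free["b"]) out <- c(out, gb) else gth <- gth + sum(gb * p$bs) * tbar
    if (free["Q"]) out <- c(out, gq) else gth <- gth + sum(gq * vech(p$Qs)) * tbar
    if (free["theta"]) out <- c(out, gth)
    out
  }
  scale0 <- pmax(abs(par0), 1e-4 * max(abs(par0), 1e-12))
  first_method <- if (length(par0) > 1L) "Nelder-Mead" else "BFGS"
  opt <- stats::optim(par0, nll, gr = if (first_method == "BFGS") nll_grad,
                      method = first_method,
                      control = list(maxit = ctrl$maxit, reltol = ctrl$reltol,
                                     parscale = scale0))
  for (r in seq_len(ctrl$restarts)) {
    scale1 <- pmax(abs(opt$par), 1e-4 * max(abs(opt$par), 1e-12))
    opt2 <- stats::optim(opt$par, nll, gr = nll_grad, method = "BFGS",
                         control = list(maxit = 300L, reltol = 1e-12,
                                        parscale = scale1))
    if (is.finite(opt2$value) && opt2$value <= opt$value) opt <- opt2
  }
  if (!is.finite(opt$value))
    stop("convergence error: hazard likelihood is not finite at the final iterate")

  p <- unpack(opt$par)
  sc <- exp(p$theta * tbar)
  mu0 <- p$mu0s / sc
  b <- p$bs / (sy * sc)
  Q <- p$Qs / (tcrossprod(sy) * sc)
  Q <- (Q + t(Q)) / 2
  # validate non-negativity of the fitted hazard over the observed range
  brk <- mu0 + drop(Y %*% b) + rowSums((Y %*% Q) * Y)
  if (min(brk) < -1e-12 * max(abs(brk), 1))
    warning("fitted hazard is negative for some observed biomarker values")
  list(mu0 = mu0, b = unname(b), Q = unname(Q), theta = p$theta,
       nll = opt$value, convergence = opt$convergence, n_events = sum(case))
}

# starting values on the internal (scaled/centred) parameterization
hazard_start_values <- function(Z, case, tc, dts, k) {
  n <- length(case)
  rate0 <- max(sum(case), 0.5) / sum(dts)
  fallback <- list(mu0s = rate0, bs = rep(0, k),
                   Qs = diag(1e-3 * rate0, k), theta = 0.02)
  prods <- do.call(cbind, lapply(seq_len(k), function(i)
    sapply(i:k, function(j) Z[, i] * Z[, j])))
  X <- cbind(Z, prods, tc)
  fit <- tryCatch(
    suppressWarnings(stats::glm.fit(cbind(1, X), case,
                                    family = stats::binomial(link = "log"),
                                    start = c(log(max(mean(case), 1e-6)),
                                              rep(0, ncol(X))))),
    error = function(e) NULL)
  if (is.null(fit) || !all(is.finite(fit$coefficients))) return(fallback)
  cf <- fit$coefficients
  theta <- unname(cf[length(cf)])
  if (!is.finite(theta) || abs(theta) > 0.5) theta <- 0.02
  # approximate the bracket: exp(linear predictor without the age term) is a
  # per-interval death probability; convert to a rate and project onto the
  # quadratic basis [1, z, products] by least squares
  eta <- drop(cbind(1, X[, -ncol(X), drop = FALSE]) %*% cf[-length(cf)])
  g <- pmin(pmax(exp(eta), 1e-12), 1 - 1e-9)
  rate <- -log(1 - g) / dts
  Bq <- cbind(1, Z, prods)
  beta <- tryCatch(qr.coef(qr(Bq), rate), error = function(e) NULL)
  if (is.null(beta) || any(!is.finite(beta))) return(fallback)
  mu0s <- beta[1]
  bs <- beta[1 + seq_len(k)]
  qv <- beta[-(seq_len(k + 1L))]
  Qs <- matrix(0, k, k); pos <- 1L
  for (i in seq_len(k)) for (j in i:k) {
    Qs[i, j] <- Qs[j, i] <- if (i == j) qv[pos] else qv[pos] / 2
    pos <- pos + 1L
  }
  if (mu0s <= 0) mu0s <- rate0
  list(mu0s = unname(mu0s), bs = unname(bs), Qs = Qs, theta = theta)
}

#' Fit the full discrete-time SPM
#'
#' Runs [fit_autoregression()] and [fit_discrete_hazard()] on a
#' fixed-interval paired table and assembles both parameterizations: the
#' native discrete one and, when the observation interval is one year, the
#' continuous-time equivalent obtained by [discrete_to_continuous()].
#'
#' @param pairs a fixed-interval `paired_observations` table.
#' @param fix,control passed to [fit_discrete_hazard()].
#' @return list with elements `discrete` ([discrete_params()]),
#'   `continuous` ([continuous_params()] or `NULL` when the interval is not
#'   one year), and `hazard_fit` (optimizer report).
#' @export
fit_discrete <- function(pairs, fix = list(), control = list()) {
  ar <- fit_autoregression(pairs)
  hz <- fit_discrete_hazard(pairs, fix = fix, control = control)
  d <- discrete_params(u = ar$u, R = ar$R, Sigma = ar$Sigma,
                       mu0 = hz$mu0, b = hz$b, Q = hz$Q, theta = hz$theta)
  dts <- pairs$t2 - pairs$t1
  step <- stats::median(dts[is.finite(dts)])
  cont <- NULL
  if (abs(step - 1) < 1e-6) {
    cont <- tryCatch(discrete_to_continuous(d),
                     error = function(e) { warning(conditionMessage(e)); NULL })
  } else {
    warning("observation interval differs from 1; continuous-form conversion skipped")
  }
  list(discrete = d, continuous = cont,
       hazard_fit = hz[c("nll", "convergence", "n_events")])
}
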