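#' Survival of the undivided state: closed form
#'
#' Probability that a cell starting at size \eqn{s_0} has not divided by
#' time `t` under the linear hazard \eqn{h = k s_0 e^{\mu t}}:
#' \deqn{P_0(t) = \exp\!\left[-\frac{k s_0}{\mu}\left(e^{\mu t} - 1\right)
#'   \right].}
#' Strictly decreasing in `t`, tends to 0 as \eqn{t \to \infty}.
#'
#' @param t Time(s), >= 0.
#' @param params A [model_params()] object (`lambda` must be 1; the closed
#'   form is specific to the linear rate).
#' @return Probability vector of the same length as `t`.
#' @examples
#' p <- model_params(mu = log(2), k = log(2), s0 = 1)
#' p0_closed_form(1, p)  # exp(-1): theta = 1, e^{mu*tau} = 2
#' @export
p0_closed_form <- function(t, params) {
  stopifnot(inherits(params, "crm_params"))
  if (params$lambda != 1)
    stop("closed form requires lambda = 1", call. = FALSE)
  if (!is.numeric(t) || any(!is.finite(t)) || any(t < 0))
    stop("'t' must be finite and nonnegative", call. = FALSE)
  exp(-(params$k * params$s0 / params$mu) * (exp(params$mu * t) - 1))
}

# Cumulative integral of f sampled on a uniform grid of step h, by the
# 4-point Newton-Cotes rule per interval (cubic through the two points of
# the interval and one neighbour each side); O(h^4) globally.
cumquad_uniform <- function(f, h) {
  n <- length(f)
  if (n < 4L) {
    incr <- h * (f[-n] + f[-1L]) / 2
    return(cumsum(c(0, incr)))
  }
  incr <- numeric(n - 1L)
  m <- 2:(n - 2L)
  incr[m] <- h * (-f[m - 1L] + 13 * f[m] + 13 * f[m + 1L] - f[m + 2L]) / 24
  incr[1L] <- h * (9 * f[1L] + 19 * f[2L] - 5 * f[3L] + f[4L]) / 24
  incr[n - 1L] <- h * (f[n - 3L] - 5 * f[n - 2L] + 19 * f[n - 1L] +
                         9 * f[n]) / 24
  cumsum(c(0, incr))
}

# One pass of the analytic recursion on a uniform fine grid: given all
# P_0..P_imax sampled on t_fine, not exported.
recursion_on_grid <- function(imax, t_fine, params) {
  mu <- params$mu; ks0 <- params$k * params$s0
  h <- t_fine[2L] - t_fine[1L]
  emut <- exp(mu * t_fine)
  out <- matrix(0, nrow = length(t_fine), ncol = imax + 1L)
  out[, 1L] <- exp(-(ks0 / mu) * (emut - 1))
  if (imax >= 1L) for (i in seq_len(imax)) {
    b <- ks0 / (mu * 2^i)
    # P_i(t) = (ks0/2^{i-1}) exp(-b e^{mu t}) \int_0^t e^{mu t' + b e^{mu t'}}
    #          P_{i-1}(t') dt'; evaluated in log space for stability
    expo <- mu * t_fine + b * emut
    off <- max(expo)
    J <- cumquad_uniform(exp(expo - off) * out[, i], h)
    logC <- log(ks0) - (i - 1) * log(2)
    Pi <- ifelse(J > 0, exp(logC - b * emut + off + log(J)), 0)
    out[, i + 1L] <- Pi
  }
  out
}

#' Division-count probabilities by the analytic quadrature recursion
#'
#' Evaluates the recursive closed-form solution of the division-counting
#' master equation,
#' \deqn{P_i(t) = \frac{k s_0}{2^{i-1}}
#'   \exp\!\left[-\frac{k s_0}{\mu 2^i} e^{\mu t}\right]
#'   \int_0^t K(t')\, P_{i-1}(t')\, dt', \qquad
#'   K(t') = \exp\!\left[\mu t' + \frac{k s_0}{\mu 2^i} e^{\mu t'}\right],}
#' starting from the closed-form \eqn{P_0}. The cumulative integral is
#' computed on an internally refined uniform grid with a fourth-order rule;
#' the refinement is doubled until two successive evaluations of
#' \eqn{P_i} agree within `quad_tol` in sup norm.
#'
#' @param i Division count, >= 1.
#' @param t_grid Strictly increasing, uniformly spaced times starting at 0.
#' @param params A [model_params()] object with `lambda = 1`.
#' @param quad_tol Sup-norm tolerance of the quadrature, default 1e-9.
#' @return Numeric vector \eqn{P_i} over `t_grid`; the full matrix
#'   \eqn{P_0 \dots P_i} is attached as attribute `"P_all"`.
#' @export
p_i_recursive <- function(i, t_grid, params, quad_tol = 1e-9) {
  stopifnot(inherits(params, "crm_params"))
  if (params$lambda != 1)
    stop("the analytic recursion requires lambda = 1", call. = FALSE)
  if (!is.numeric(i) || length(i) != 1L || i < 1 || i != round(i))
    stop("'i' must be a positive integer", call. = FALSE)
  check_uniform_grid(t_grid)
  n <- length(t_grid)
  refine <- 4L
  prev <- NULL
  repeat {
    t_fine <- seq(t_grid[1L], t_grid[n], length.out = (n - 1L) * refine + 1L)
    P <- recursion_on_grid(i, t_fine, params)
    idx <- seq(1L, length(t_fine), by = refine)
    cur <- P[idx, , drop = FALSE]
    if (!is.null(prev) && max(abs(cur - prev)) <= quad_tol) break
    if (refine > 64L)
      stop("quadrature failed to reach quad_tol = ", quad_tol,
           "; last sup-norm change ", signif(max(abs(cur - prev)), 3),
           call. = FALSE)
    prev <- cur
    refine <- refine * 2L
  }
  if (any(cur < -quad_tol) || any(cur > 1 + quad_tol))
    stop("recursion produced values outside [0, 1]", call. = FALSE)
  cur <- pmin(pmax(cur, 0), 1)
  structure(cur[, i + 1L], P_all = cur)
}

check_uniform_grid <- function(t_grid) {
  if (!is.numeric(t_grid) || length(t_grid) < 2L || any(diff(t_grid) <= 0))
    stop("'t_grid' must be strictly increasing with >= 2 points",
         call. = FALSE)
  dt <- diff(t_grid)
  if (max(abs(dt - dt[1L])) > 1e-8 * dt[1L])
    stop("'t_grid' must be uniformly spaced", call. = FALSE)
  if (abs(t_grid[1L]) > .Machine$double.eps)
    stop("'t_grid' must start at 0", call. = FALSE)
  invisible(TRUE)
}

new_division_count_distribution <- function(t_grid, P, params,
                                            rtol, atol, method) {
  leak <- 1 - rowSums(P)
  structure(
    list(t_grid = t_grid, P = P, N = ncol(P) - 1L, leak = leak,
         params = params, rtol = rtol, atol = atol, method = method),
    class = "division_count_distribution")
}

#' @export
print.division_count_distribution <- function(x, ...) {
  nt <- length(x$t_grid)
  cat("Division-count distribution (truncated master-equation solution)\n")
  cat(sprintf("  states i = 0..%d, %d times on [%g, %g]  (%s)\n",
              x$N, nt, x$t_grid[1L], x$t_grid[nt], x$method))
  cat(sprintf("  truncation leak at final time: %.3g\n", x$leak[nt]))
  invisible(x)
}

#' Finite state projection of the division-counting master equation
#'
#' Integrates the truncated master equation
#' \deqn{\frac{dP_0}{dt} = -k s_0 e^{\mu t} P_0, \qquad
#'   \frac{dP_i}{dt} = \frac{k s_0 e^{\mu t}}{2^{i-1}} P_{i-1}
#'     - \frac{k s_0 e^{\mu t}}{2^{i}} P_i, \quad i = 1 \dots N,}
#' with \eqn{P_i(0) = \delta_{i,0}}, no inflow from states beyond \eqn{N}.
#' Probability flowing past state \eqn{N} accumulates as *leak*
#' \eqn{1 - \sum_i P_i(t)}, a computable bound on the truncation error of
#' the whole distribution; it is tracked, never renormalized away.
#'
#' For the generalized hazard \eqn{h = k s^\lambda} the rate out of state
#' \eqn{i} is \eqn{k (s_0 e^{\mu t} / 2^i)^\lambda}.
#'
#' @param params A [model_params()] object.
#' @param N Truncation index, >= 1.
#' @param t_grid Output times, starting at 0, increasing.
#' @param ode_rtol,ode_atol Relative / absolute integrator tolerances;
#'   defaults 1e-9 / 1e-12 so probabilities near 1e-6 are resolved.
#' @return A `division_count_distribution`: times, raw probability matrix
#'   `P` (rows = times, columns = states 0..N), truncation index, per-time
#'   leak, and solver metadata. Small negative round-off values are kept in
#'   `P` (conservation checks need them); reporting helpers clamp to 0.
#' @examples
#' p <- model_params(mu = log(2), k = log(2), s0 = 1)
#' d <- fsp_propagate(p, N = 20, t_grid = seq(0, 7, length.out = 141))
#' d$leak[141]  # truncation error bound at t = 7 tau
#' @export
fsp_propagate <- function(params, N, t_grid,
                          ode_rtol = 1e-9, ode_atol = 1e-12) {
  stopifnot(inherits(params, "crm_params"))
  if (!is.numeric(N) || length(N) != 1L || N < 1 || N != round(N))
    stop("'N' must be a positive integer", call. = FALSE)
  if (!is.numeric(t_grid) || length(t_grid) < 2L ||
      abs(t_grid[1L]) > .Machine$double.eps || any(diff(t_grid) <= 0))
    stop("'t_grid' must start at 0 and be strictly increasing",
         call. = FALSE)
  mu <- params$mu; k <- params$k; s0 <- params$s0; lam <- params$lambda
  # outflow rate of state i at t: k * (s0 e^{mu t} / 2^i)^lambda
  wout <- k * (s0 / 2^(0:N))^lam
  ii <- seq_len(N)
  deriv <- function(t, P, parms) {
    r <- wout * exp(lam * mu * t)
    flow <- r * P
    dP <- -flow
    dP[ii + 1L] <- dP[ii + 1L] + flow[ii]
    list(dP)
  }
  sol <- deSolve::ode(y = c(1, rep(0, N)), times = t_grid, func = deriv,
                      parms = NULL, method = "lsoda",
                      rtol = ode_rtol, atol = ode_atol)
  if (attr(sol, "istate")[1L] < 0)
    stop("ODE solver failed to converge", call. = FALSE)
  P <- unname(sol[, -1L, drop = FALSE])
  new_division_count_distribution(t_grid, P, params, ode_rtol, ode_atol,
                                  method = "fsp-lsoda")
}

#' Finite state projection via an exact matrix exponential
#'
#' The time substitution \eqn{x = e^{\mu t}} makes the truncated master
#' equation autonomous with a constant lower-bidiagonal generator \eqn{A}
#' (at \eqn{\lambda = 1}), so
#' \eqn{P(t) = \exp\!\left[A\,(e^{\mu t} - 1)/\mu\right] P(0)} exactly.
#' Provided as an independent cross-check of [fsp_propagate()].
#'
#' @inheritParams fsp_propagate
#' @return A `division_count_distribution` (method `"fsp-expm"`).
#' @export
fsp_propagate_expm <- function(params, N, t_grid) {
  stopifnot(inherits(params, "crm_params"))
  if (params$lambda != 1)
    stop("the matrix-exponential route requires lambda = 1", call. = FALSE)
  if (!is.numeric(N) || length(N) != 1L || N < 1 || N != round(N))
    stop("'N' must be a positive integer", call. = FALSE)
  mu <- params$mu
  w <- params$k * params$s0 / 2^(0:N)
  A <- matrix(0, N + 1L, N + 1L)
  diag(A) <- -w
  A[cbind(2:(N + 1L), 1:N)] <- w[1:N]
  P <- matrix(0, length(t_grid), N + 1L)
  for (m in seq_along(t_grid)) {
    u <- (exp(mu * t_grid[m]) - 1) / mu
    E <- as.matrix(Matrix::expm(A * u))
    P[m, ] <- E[, 1L]
  }
  new_division_count_distribution(t_grid, P, params, NA_real_, NA_real_,
                                  method = "fsp-expm")
}

#' Smallest truncation meeting a leak bound
#'
#' Searches (by doubling, then bisecting down) for the smallest truncation
#' index `N` whose leak at `t_final` does not exceed `leak_bound`.
#'
#' @param params A [model_params()] object.
#' @param t_final Final time of interest, >= 0.
#' @param leak_bound Acceptable truncation deficit, in (0, 1).
#' @param N_max Hard cap on the search, default 512.
#' @param ode_rtol,ode_atol Passed to [fsp_propagate()].
#' @return The truncation index N.
#' @export
fsp_auto_truncate <- function(params, t_final, leak_bound, N_max = 512L,
                              ode_rtol = 1e-9, ode_atol = 1e-12) {
  stopifnot(inherits(params, "crm_params"))
  if (!is.numeric(leak_bound) || length(leak_bound) != 1L ||
      leak_bound <= 0 || leak_bound >= 1)
    stop("'leak_bound' must be in (0, 1)", call. = FALSE)
  if (!is.numeric(t_final) || length(t_final) != 1L || t_final < 0)
    stop("'t_final' must be nonnegative", call. = FALSE)
  if (t_final == 0) return(1L)
  final_leak <- function(N) {
    d <- fsp_propagate(params, N, c(0, t_final / 2, t_final),
                       ode_rtol = ode_rtol, ode_atol = ode_atol)
    d$leak[3L]
  }
  N <- 1L
  while (final_leak(N) > leak_bound) {
    if (N >= N_max)
      stop("no truncation <= N_max = ", N_max, " meets leak bound ",
           leak_bound, call. = FALSE)
    N <- min(2L * N, N_max)
  }
  lo <- max(1L, N %/% 2L); hi <- N  # smallest feasible N is in (lo, hi]
  while (lo < hi - 1L) {
    mid <- (lo + hi) %/% 2L
    if (final_leak(mid) <= leak_bound) hi <- mid else lo <- mid
  }
  if (lo == 1L && final_leak(1L) <= leak_bound) return(1L)
  hi
}

#' Mean and variance of the division count over time
#'
#' \eqn{\langle n\rangle(t) = \sum_i i P_i(t)} and
#' \eqn{\mathrm{var}(n)(t) = \sum_i (i - \langle n\rangle)^2 P_i(t)},
#' computed on the truncated support. Rows where the leak exceeds
#' `10 * ode_rtol` carry `leak_flag = TRUE`: the truncated moments are then
#' not trustworthy to integrator precision.
#'
#' @param dist A `division_count_distribution`.
#' @return A `moment_series` data frame with columns
#'   `t`, `mean`, `var`, `leak`, `leak_flag`; attribute `quantity = "n"`.
#' @export
moments_n <- function(dist) {
  stopifnot(inherits(dist, "division_count_distribution"))
  P <- pmax(dist$P, 0)
  i <- 0:dist$N
  mn <- as.numeric(P %*% i)
  m2 <- as.numeric(P %*% i^2)
  vr <- m2 - mn^2
  thr <- if (is.finite(dist$rtol)) 10 * dist$rtol else 1e-8
  structure(
    data.frame(t = dist$t_grid, mean = mn, var = pmax(vr, 0),
               leak = dist$leak, leak_flag = dist$leak > thr),
    quantity = "n", class = c("moment_series", "data.frame"))
}

#' Asymptotic translation-invariance residual
#'
#' For large division counts the pulses \eqn{P_i} become translates of one
#' another by one doubling time: \eqn{\|P_i(t) - P_{i-1}(t - \tau)\| \to 0}
#' as \eqn{i \to \infty}. This returns the sup norm of that difference over
#' the overlapping part of the grid; it decreases with `i` once the early
#' transient has passed.
#'
#' @param dist A `division_count_distribution` whose uniform grid spans at
#'   least \eqn{[\tau, t_{final}]} with a step that divides \eqn{\tau}.
#' @param i Division count, 1 <= i <= N.
#' @return Nonnegative residual \eqn{\sup_t |P_i(t) - P_{i-1}(t-\tau)|}.
#' @export
periodicity_residual <- function(dist, i) {
  stopifnot(inherits(dist, "division_count_distribution"))
  if (!is.numeric(i) || length(i) != 1L || i < 1 || i > dist$N ||
      i != round(i))
    stop("'i' must be an integer in [1, N]", call. = FALSE)
  tg <- dist$t_grid
  check_uniform_grid(tg)
  dt <- tg[2L] - tg[1L]
  tau <- dist$params$tau
  m <- tau / dt
  if (abs(m - round(m)) > 1e-6)
    stop("grid step must divide the doubling time tau; got tau/dt = ",
         signif(m, 8), call. = FALSE)
  m <- as.integer(round(m))
  nt <- length(tg)
  if (m >= nt)
    stop("grid must span at least [tau, t_final]", call. = FALSE)
  sh <- (m + 1L):nt
  max(abs(dist$P[sh, i + 1L] - dist$P[sh - m, i]))
}
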