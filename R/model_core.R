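#' Model parameters for the continuous-rate division model
#'
#' Bundles the parameters of a cell that grows exponentially in size,
#' \eqn{ds/dt = \mu s}, and divides symmetrically with splitting rate
#' (division hazard) \eqn{h = k s^\lambda}. For the linear rate
#' (\eqn{\lambda = 1}) the model is the continuous-rate counterpart of the
#' adder strategy: the size added per cycle is exponential with mean
#' \eqn{\bar\Delta = \mu / k}, independent of birth size.
#'
#' Derived quantities are attached on construction: the doubling time
#' \eqn{\tau = \ln 2 / \mu}, the mean added size \eqn{\bar\Delta = \mu/k}
#' (meaningful only at \eqn{\lambda = 1}; `NA` otherwise) and the
#' dimensionless rate \eqn{\theta = k s_0 / \mu} that, together with
#' \eqn{\mu t}, fully determines the division-count dynamics.
#'
#' @param mu Exponential growth rate (1/time), > 0.
#' @param k Splitting-rate constant (1/(size^lambda * time)), > 0.
#' @param s0 Initial (birth) size, > 0.
#' @param lambda Rate exponent of the generalized hazard `k * s^lambda`,
#'   > 0. Default 1 (linear rate, adder behaviour).
#' @return An object of class `crm_params`.
#' @examples
#' p <- model_params(mu = log(2), k = log(2), s0 = 1)
#' p$tau        # doubling time = 1
#' p$delta_bar  # mean added size = 1
#' @export
model_params <- function(mu, k, s0, lambda = 1) {
  for (nm in c("mu", "k", "s0", "lambda")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop(sprintf("'%s' must be a single finite positive number", nm),
           call. = FALSE)
  }
  structure(
    list(mu = mu, k = k, s0 = s0, lambda = lambda,
         tau = doubling_time(mu),
         delta_bar = if (lambda == 1) mean_added_size(mu, k) else NA_real_,
         theta = k * s0^lambda / mu),
    class = "crm_params")
}

#' @export
print.crm_params <- function(x, ...) {
  cat("Continuous-rate division model parameters\n")
  cat(sprintf("  mu = %g (doubling time tau = %g)\n", x$mu, x$tau))
  cat(sprintf("  k  = %g, lambda = %g  (hazard h = k * s^lambda)\n",
              x$k, x$lambda))
  cat(sprintf("  s0 = %g   theta = k*s0^lambda/mu = %g\n", x$s0, x$theta))
  if (!is.na(x$delta_bar))
    cat(sprintf("  mean added size mu/k = %g\n", x$delta_bar))
  invisible(x)
}

#' Doubling time of exponential growth
#'
#' @param mu Growth rate, > 0.
#' @return \eqn{\tau = \ln 2 / \mu}.
#' @examples
#' doubling_time(log(2))  # 1
#' @export
doubling_time <- function(mu) {
  if (!is.numeric(mu) || length(mu) != 1L || !is.finite(mu) || mu <= 0)
    stop("'mu' must be a single finite positive number", call. = FALSE)
  log(2) / mu
}

#' Mean added size per division cycle (linear rate)
#'
#' Under the linear splitting rate `h = k*s` the size added between birth
#' and division is exponentially distributed with mean \eqn{\mu / k},
#' independent of birth size (the adder property).
#'
#' @param mu Growth rate, > 0.
#' @param k Splitting-rate constant, > 0.
#' @return \eqn{\bar\Delta = \mu / k}.
#' @export
mean_added_size <- function(mu, k) {
  if (!is.numeric(mu) || length(mu) != 1L || !is.finite(mu) || mu <= 0)
    stop("'mu' must be a single finite positive number", call. = FALSE)
  if (!is.numeric(k) || length(k) != 1L || !is.finite(k) || k <= 0)
    stop("'k' must be a single finite positive number", call. = FALSE)
  mu / k
}

#' Exact interdivision-time draw from the size-dependent hazard
#'
#' Inverse-transform sampling of the waiting time until division for a cell
#' born at size `birth_size` and growing exponentially, under the hazard
#' \eqn{h(t) = k (s_b e^{\mu t})^\lambda}. The cumulative hazard is
#' \eqn{H(t) = \frac{k s_b^\lambda}{\lambda\mu}(e^{\lambda\mu t} - 1)}, so
#' with a unit-mean exponential draw \eqn{E} the division time solves
#' \eqn{H(T) = E}:
#' \deqn{T = \frac{1}{\lambda\mu}\,
#'   \ln\!\left(1 + \frac{\lambda\mu E}{k s_b^\lambda}\right).}
#' At \eqn{\lambda = 1} the implied added size
#' \eqn{\Delta = s_b(e^{\mu T} - 1) = (\mu/k) E} is exponential with mean
#' \eqn{\mu/k} whatever the birth size — the adder decorrelation.
#'
#' The unit-exponential draw is an argument (not an RNG) so that all seeding
#' lives in the simulator; the draw may be a vector, in which case a vector
#' of times is returned.
#'
#' @param birth_size Size at birth, > 0.
#' @param params A [model_params()] object.
#' @param unit_exponential_draw One or more realizations of a unit-mean
#'   exponential variable, >= 0.
#' @return Interdivision time(s), same length as the draw.
#' @examples
#' p <- model_params(mu = log(2), k = log(2), s0 = 1)
#' # accumulated hazard k*s0/mu at T means division exactly at doubling:
#' sample_interdivision_time(1, p, p$k * 1 / p$mu)  # = tau = 1
#' @export
sample_interdivision_time <- function(birth_size, params,
                                      unit_exponential_draw) {
  stopifnot(inherits(params, "crm_params"))
  if (!is.numeric(birth_size) || length(birth_size) != 1L ||
      !is.finite(birth_size) || birth_size <= 0)
    stop("'birth_size' must be a single finite positive number",
         call. = FALSE)
  E <- unit_exponential_draw
  if (!is.numeric(E) || any(!is.finite(E)) || any(E < 0))
    stop("'unit_exponential_draw' must be finite and nonnegative",
         call. = FALSE)
  lm_ <- params$lambda * params$mu
  log1p(lm_ * E / (params$k * birth_size^params$lambda)) / lm_
}

#' Serialize model parameters to a flat JSON config
#'
#' @param params A [model_params()] object.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return The JSON string, invisibly when written to `path`.
#' @export
params_to_json <- function(params, path = NULL) {
  stopifnot(inherits(params, "crm_params"))
  x <- list(mu = params$mu, k = params$k, s0 = params$s0,
            lambda = params$lambda)
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Read model parameters from a flat JSON config
#'
#' Accepts `{"mu": ..., "k": ..., "s0": ..., "lambda": ...}`; `lambda`
#' defaults to 1 when absent.
#'
#' @param path File path or a literal JSON string.
#' @return A [model_params()] object.
#' @export
params_from_json <- function(path) {
  x <- jsonlite::fromJSON(path)
  for (nm in c("mu", "k", "s0"))
    if (is.null(x[[nm]])) stop("config misses field '", nm, "'",
                               call. = FALSE)
  model_params(mu = x$mu, k = x$k, s0 = x$s0,
               lambda = if (is.null(x$lambda)) 1 else x$lambda)
}
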