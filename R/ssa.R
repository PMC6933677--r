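#' Initial-size specification
#'
#' Describes how birth sizes at t = 0 are distributed across an ensemble:
#' a fixed value, uniform on `[a, b]`, lognormal, or an explicit atom list.
#'
#' @param type One of `"fixed"`, `"uniform"`, `"lognormal"`, `"atoms"`.
#' @param s0 Fixed size (type `"fixed"`).
#' @param min,max Bounds (type `"uniform"`).
#' @param meanlog,sdlog Log-scale parameters (type `"lognormal"`).
#' @param values,weights Atom sizes and probabilities (type `"atoms"`);
#'   weights are normalized to sum to 1.
#' @return An object of class `initial_size_spec`.
#' @export
initial_size_spec <- function(type = c("fixed", "uniform", "lognormal",
                                       "atoms"),
                              s0 = NULL, min = NULL, max = NULL,
                              meanlog = NULL, sdlog = NULL,
                              values = NULL, weights = NULL) {
  type <- match.arg(type)
  spec <- switch(type,
    fixed = {
      if (is.null(s0) || s0 <= 0) stop("'s0' must be positive",
                                       call. = FALSE)
      list(type = type, s0 = s0)
    },
    uniform = {
      if (is.null(min) || is.null(max) || min <= 0 || max <= min)
        stop("need 0 < min < max", call. = FALSE)
      list(type = type, min = min, max = max)
    },
    lognormal = {
      if (is.null(meanlog) || is.null(sdlog) || sdlog < 0)
        stop("need meanlog and sdlog >= 0", call. = FALSE)
      list(type = type, meanlog = meanlog, sdlog = sdlog)
    },
    atoms = {
      if (is.null(values) || any(values <= 0))
        stop("'values' must be positive", call. = FALSE)
      if (is.null(weights)) weights <- rep(1, length(values))
      if (length(weights) != length(values) || any(weights < 0) ||
          sum(weights) <= 0)
        stop("'weights' must be nonnegative, matching 'values'",
             call. = FALSE)
      list(type = type, values = values, weights = weights / sum(weights))
    })
  structure(spec, class = "initial_size_spec")
}

# Draw n initial sizes from a spec using the current RNG state.
sample_initial_size <- function(spec, n = 1L) {
  stopifnot(inherits(spec, "initial_size_spec"))
  switch(spec$type,
         fixed = rep(spec$s0, n),
         uniform = stats::runif(n, spec$min, spec$max),
         lognormal = stats::rlnorm(n, spec$meanlog, spec$sdlog),
         atoms = sample(spec$values, n, replace = TRUE,
                        prob = spec$weights))
}

# Deterministic equal-probability quantile nodes of a spec (for mixtures).
initial_size_nodes <- function(spec, n_nodes) {
  stopifnot(inherits(spec, "initial_size_spec"))
  if (n_nodes < 1L) stop("'n_nodes' must be >= 1", call. = FALSE)
  p <- (seq_len(n_nodes) - 0.5) / n_nodes
  switch(spec$type,
         fixed = list(s0 = spec$s0, w = 1),
         uniform = list(s0 = stats::qunif(p, spec$min, spec$max),
                        w = rep(1 / n_nodes, n_nodes)),
         lognormal = list(s0 = stats::qlnorm(p, spec$meanlog, spec$sdlog),
                          w = rep(1 / n_nodes, n_nodes)),
         atoms = list(s0 = spec$values, w = spec$weights))
}

#' Ensemble simulation configuration
#'
#' @param n_cells Ensemble size, >= 1.
#' @param t_final Time horizon, > 0.
#' @param seed RNG seed (integer); the same seed and configuration give
#'   bit-identical output.
#' @param record_grid Output times within `[0, t_final]`; default 512
#'   uniform points spanning the horizon.
#' @param initial_size An [initial_size_spec()]; default a point mass that
#'   must match the model's `s0` at simulation time.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_cells, t_final, seed,
                              record_grid = NULL, initial_size = NULL) {
  if (!is.numeric(n_cells) || n_cells < 1 || n_cells != round(n_cells))
    stop("'n_cells' must be a positive integer", call. = FALSE)
  if (!is.numeric(t_final) || t_final <= 0)
    stop("'t_final' must be positive", call. = FALSE)
  if (is.null(record_grid))
    record_grid <- seq(0, t_final, length.out = 512L)
  if (any(record_grid < 0) || any(record_grid > t_final) ||
      any(diff(record_grid) <= 0))
    stop("'record_grid' must be increasing within [0, t_final]",
         call. = FALSE)
  structure(list(n_cells = as.integer(n_cells), t_final = t_final,
                 seed = as.integer(seed), record_grid = record_grid,
                 initial_size = initial_size),
            class = "simulation_config")
}

#' Simulate one mother-machine lineage exactly
#'
#' Alternates exact interdivision-time draws (inverse transform of the
#' cumulative hazard, [sample_interdivision_time()]) with symmetric halving
#' at division, keeping one daughter per division. Between events the size
#' grows exponentially, so along the lineage
#' \eqn{s(t) = s_0 e^{\mu t} / 2^{n(t)}} exactly. Event times are drawn in
#' continuous time; there is no discretization error.
#'
#' @param params A [model_params()] object.
#' @param t_final Simulation horizon, > 0.
#' @param birth_size Size at t = 0; defaults to `params$s0`.
#' @param draws Optional vector of unit-exponential draws consumed one per
#'   cycle (for deterministic forcing in tests); when exhausted, or `NULL`,
#'   draws come from the current RNG via `rexp(1)`.
#' @return A `lineage`: data frame `records` of completed cycles
#'   (generation, birth_time, birth_size, division_size, added_size,
#'   interdivision_time), the vector `division_times`, and metadata.
#' @examples
#' p <- model_params(mu = log(2), k = log(2), s0 = 1)
#' # forcing each accumulated hazard to k*s_b/mu divides exactly at tau:
#' lin <- simulate_lineage(p, 3.5, draws = rep(p$k * 1 / p$mu, 10))
#' lin$division_times  # 1, 2, 3
#' @export
simulate_lineage <- function(params, t_final, birth_size = params$s0,
                             draws = NULL) {
  stopifnot(inherits(params, "crm_params"))
  if (!is.numeric(t_final) || t_final <= 0)
    stop("'t_final' must be positive", call. = FALSE)
  sb <- birth_size
  t <- 0; gen <- 0L; di <- 0L
  rec <- vector("list", 64L)
  repeat {
    di <- di + 1L
    E <- if (!is.null(draws) && di <= length(draws)) draws[di]
         else stats::rexp(1)
    Tdiv <- sample_interdivision_time(sb, params, E)
    if (t + Tdiv > t_final) break
    sd_ <- sb * exp(params$mu * Tdiv)
    gen <- gen + 1L
    rec[[gen]] <- c(gen, t, sb, sd_, sd_ - sb, Tdiv)
    t <- t + Tdiv
    sb <- sd_ / 2   # symmetric division, no partitioning error
  }
  records <- if (gen > 0L) {
    m <- do.call(rbind, rec[seq_len(gen)])
    data.frame(generation = as.integer(m[, 1L]), birth_time = m[, 2L],
               birth_size = m[, 3L], division_size = m[, 4L],
               added_size = m[, 5L], interdivision_time = m[, 6L])
  } else {
    data.frame(generation = integer(), birth_time = numeric(),
               birth_size = numeric(), division_size = numeric(),
               added_size = numeric(), interdivision_time = numeric())
  }
  structure(list(records = records,
                 division_times = records$birth_time +
                   records$interdivision_time,
                 s0 = birth_size, params = params, t_final = t_final),
            class = "lineage")
}

#' Division count of a lineage at given times
#' @param lineage A `lineage`.
#' @param t Times within the simulated horizon.
#' @return Integer vector n(t).
#' @export
lineage_count <- function(lineage, t) {
  stopifnot(inherits(lineage, "lineage"))
  findInterval(t, lineage$division_times)
}

#' Size along a lineage at given times
#'
#' Uses the identity \eqn{s(t) = s_0 e^{\mu t} / 2^{n(t)}}.
#' @inheritParams lineage_count
#' @return Numeric vector s(t).
#' @export
lineage_size <- function(lineage, t) {
  n <- lineage_count(lineage, t)
  lineage$s0 * exp(lineage$params$mu * t) / 2^n
}

#' Simulate an ensemble of independent lineages
#'
#' Runs `n_cells` independent mother-machine lineages, each on its own
#' L'Ecuyer-CMRG substream derived from the seed (reproducible and order-
#' independent). Returns per-time empirical moments of the division count
#' `n` and the size `s` with normal-approximation 95% confidence
#' half-widths (for the variance, via a variance-of-variance estimate),
#' the pooled cycle table, and the per-time division-count histogram.
#'
#' @param config A [simulation_config()].
#' @param params A [model_params()] object.
#' @return An `ensemble_summary`: data frame `summary` with columns
#'   `t, mean_n, var_n, ci_n, mean_s, var_s, ci_s`; `counts` matrix of
#'   division-count occupancies (rows = grid times); `cycles` pooled
#'   cycle table; `n_cells`; the `config` and `params` used.
#' @export
simulate_ensemble <- function(config, params) {
  stopifnot(inherits(config, "simulation_config"),
            inherits(params, "crm_params"))
  spec <- config$initial_size
  if (is.null(spec)) spec <- initial_size_spec("fixed", s0 = params$s0)
  grid <- config$record_grid
  nt <- length(grid); nc <- config$n_cells
  nmax <- 128L  # histogram cap; far beyond any mass for practical horizons
  counts <- matrix(0L, nt, nmax + 1L)
  sums <- matrix(0, nt, 8L)  # n, n^2, n^3, n^4, s, s^2, s^3, s^4
  cyc <- vector("list", nc)

  old_kind <- RNGkind()
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    RNGkind(old_kind[1L], old_kind[2L], old_kind[3L])
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(config$seed, kind = "L'Ecuyer-CMRG")
  stream <- get(".Random.seed", globalenv())

  for (cell in seq_len(nc)) {
    assign(".Random.seed", stream, globalenv())
    sb0 <- sample_initial_size(spec, 1L)
    lin <- simulate_lineage(params, config$t_final, birth_size = sb0)
    n_t <- lineage_count(lin, grid)
    s_t <- sb0 * exp(params$mu * grid) / 2^n_t
    idx <- cbind(seq_len(nt), pmin(n_t, nmax) + 1L)
    counts[idx] <- counts[idx] + 1L
    sums <- sums + cbind(n_t, n_t^2, n_t^3, n_t^4, s_t, s_t^2, s_t^3, s_t^4)
    if (nrow(lin$records) > 0L)
      cyc[[cell]] <- cbind(cell, as.matrix(lin$records))
    stream <- parallel::nextRNGStream(stream)
  }

  cm <- sums / nc
  central <- function(m1, m2, m3, m4) {
    v <- m2 - m1^2
    mu4 <- m4 - 4 * m3 * m1 + 6 * m2 * m1^2 - 3 * m1^4
    list(var = pmax(v, 0), mu4 = pmax(mu4, 0))
  }
  nn <- central(cm[, 1L], cm[, 2L], cm[, 3L], cm[, 4L])
  ss <- central(cm[, 5L], cm[, 6L], cm[, 7L], cm[, 8L])
  # 95% CI half-widths: mean via sd/sqrt(nc); variance via var-of-variance
  ci_mean <- function(v) 1.96 * sqrt(v / nc)
  ci_var <- function(v, mu4) {
    vv <- pmax(mu4 - v^2 * (nc - 3) / (nc - 1), 0) / nc
    1.96 * sqrt(vv)
  }
  summary <- data.frame(
    t = grid,
    mean_n = cm[, 1L], var_n = nn$var, ci_n = ci_mean(nn$var),
    ci_var_n = ci_var(nn$var, nn$mu4),
    mean_s = cm[, 5L], var_s = ss$var, ci_s = ci_mean(ss$var),
    ci_var_s = ci_var(ss$var, ss$mu4))
  cycles <- if (any(!vapply(cyc, is.null, TRUE))) {
    m <- do.call(rbind, cyc)
    data.frame(cell_id = as.integer(m[, 1L]),
               generation = as.integer(m[, 2L]),
               birth_time = m[, 3L], birth_size = m[, 4L],
               division_size = m[, 5L], added_size = m[, 6L],
               interdivision_time = m[, 7L])
  } else NULL
  structure(list(summary = summary, counts = counts, cycles = cycles,
                 n_cells = nc, config = config, params = params),
            class = "ensemble_summary")
}

#' @export
print.ensemble_summary <- function(x, ...) {
  cat(sprintf(
    "Ensemble of %d lineages on [0, %g]; %d recorded times, %d cycles\n",
    x$n_cells, x$config$t_final, nrow(x$summary),
    if (is.null(x$cycles)) 0L else nrow(x$cycles)))
  invisible(x)
}

#' Empirical division-count distribution at a recorded time
#'
#' @param summary An `ensemble_summary`.
#' @param t A time present in the recording grid.
#' @return Named numeric vector of probabilities over counts `0, 1, ...`
#'   (trailing zero-mass states trimmed); sums to 1 exactly.
#' @export
empirical_division_count_dist <- function(summary, t) {
  stopifnot(inherits(summary, "ensemble_summary"))
  grid <- summary$config$record_grid
  m <- which(abs(grid - t) <= 1e-9 * max(1, abs(t)))
  if (length(m) == 0L)
    stop("'t' is not on the recording grid", call. = FALSE)
  p <- summary$counts[m[1L], ] / summary$n_cells
  keep <- max(which(p > 0))
  p <- p[seq_len(keep)]
  names(p) <- as.character(seq_len(keep) - 1L)
  p
}
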