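#' Cell-size distribution at a time as a weighted Dirac mixture
#'
#' In a fixed (mother-machine) population started at a common size
#' \eqn{s_0}, every cell with \eqn{i} completed divisions at time `t` has
#' size exactly \eqn{s_0 e^{\mu t} / 2^i}, so the size distribution is a
#' sum of weighted Dirac atoms,
#' \deqn{\rho(s \mid t) = \sum_i \delta\!\left(s -
#'   \frac{s_0 e^{\mu t}}{2^i}\right) P_i(t).}
#' Atom weights inherit the FSP leak accounting of `dist`; atoms lighter
#' than `drop_below` are omitted from the table (total mass bookkeeping is
#' unaffected: `1 - leak` includes them).
#'
#' @param dist A `division_count_distribution`.
#' @param t A time on `dist$t_grid`.
#' @param params A [model_params()] object; defaults to the one in `dist`.
#' @param drop_below Reporting threshold for atom weights, default 1e-12.
#' @return A `size_atom_set`: data frame `atoms` with columns
#'   `source_s0, i, size, size_over_s0, weight`, plus `t`, `leak` and the
#'   parameters.
#' @export
size_atoms <- function(dist, t, params = dist$params,
                       drop_below = 1e-12) {
  stopifnot(inherits(dist, "division_count_distribution"))
  m <- which(abs(dist$t_grid - t) <= 1e-9 * max(1, abs(t)))
  if (length(m) == 0L)
    stop("'t' is not on the distribution's time grid", call. = FALSE)
  m <- m[1L]
  i <- 0:dist$N
  w <- pmax(dist$P[m, ], 0)
  size <- params$s0 * exp(params$mu * dist$t_grid[m]) / 2^i
  keep <- w >= drop_below
  atoms <- data.frame(source_s0 = params$s0, i = i[keep],
                      size = size[keep],
                      size_over_s0 = size[keep] / params$s0,
                      weight = w[keep])
  structure(list(atoms = atoms, t = dist$t_grid[m],
                 leak = 1 - sum(w), params = params),
            class = "size_atom_set")
}

#' @export
print.size_atom_set <- function(x, ...) {
  cat(sprintf(
    "Dirac-mixture size distribution at t = %g: %d atoms, leak %.3g\n",
    x$t, nrow(x$atoms), x$leak))
  srcs <- unique(x$atoms$source_s0)
  if (length(srcs) > 1L)
    cat("  sources s0:", paste(signif(srcs, 6), collapse = ", "), "\n")
  invisible(x)
}

# Mean and variance of a size_atom_set; weights need not sum to 1 (leak):
# moments are of the truncated mixture, consistent with moments over P_i.
atom_moments <- function(aset) {
  w <- aset$atoms$weight; s <- aset$atoms$size
  m <- sum(w * s)
  list(mean = m, var = sum(w * (s - m)^2))
}

#' Time course of size mean and variance
#'
#' \deqn{\langle s(t)\rangle = \sum_i \frac{s_0 e^{\mu t}}{2^i} P_i(t),
#' \qquad \mathrm{var}(s(t)) = \sum_i \left(\frac{s_0 e^{\mu t}}{2^i}
#'   - \langle s\rangle\right)^2 P_i(t),}
#' computed over the truncated support of `dist`. Rows whose leak exceeds
#' `10 * ode_rtol` carry `leak_flag = TRUE`.
#'
#' @param dist A `division_count_distribution`.
#' @param params A [model_params()]; defaults to the one in `dist`.
#' @return A `moment_series` data frame with columns
#'   `t, mean, var, leak, leak_flag`; attribute `quantity = "s"`.
#' @export
size_moments <- function(dist, params = dist$params) {
  stopifnot(inherits(dist, "division_count_distribution"))
  P <- pmax(dist$P, 0)
  half <- params$s0 / 2^(0:dist$N)
  pref <- exp(params$mu * dist$t_grid)
  mn <- pref * as.numeric(P %*% half)
  m2 <- pref^2 * as.numeric(P %*% half^2)
  thr <- if (is.finite(dist$rtol)) 10 * dist$rtol else 1e-8
  structure(
    data.frame(t = dist$t_grid, mean = mn, var = pmax(m2 - mn^2, 0),
               leak = dist$leak, leak_flag = dist$leak > thr),
    quantity = "s", class = c("moment_series", "data.frame"))
}

#' Envelope of size atoms over several initial sizes
#'
#' For each initial size, solves its own division-count distribution (same
#' growth and rate constants) and collects the size atoms at time `t`,
#' tagged by their source. As the initial size sweeps an interval the atom
#' loci trace the enveloping curve of the limiting size distribution; the
#' envelope is represented as this tagged discrete union, never a fitted
#' smooth curve.
#'
#' @param s0_values Positive initial sizes.
#' @param t Evaluation time, > 0.
#' @param params_base A [model_params()]; its `mu`, `k`, `lambda` are kept,
#'   `s0` is replaced by each value in turn.
#' @param leak_bound Per-source FSP truncation bound, default 1e-8.
#' @param grid_points Points of each source's time grid, default 257.
#' @return A combined `size_atom_set` (atoms tagged by `source_s0`, each
#'   source's weights summing to `1 - leak(source)`; `leak` is the maximum
#'   over sources).
#' @export
envelope_atoms <- function(s0_values, t, params_base,
                           leak_bound = 1e-8, grid_points = 257L) {
  stopifnot(inherits(params_base, "crm_params"))
  if (any(!is.finite(s0_values)) || any(s0_values <= 0))
    stop("'s0_values' must be positive", call. = FALSE)
  if (!is.numeric(t) || length(t) != 1L || t <= 0)
    stop("'t' must be a single positive time", call. = FALSE)
  parts <- lapply(s0_values, function(s0) {
    p <- model_params(params_base$mu, params_base$k, s0,
                      params_base$lambda)
    N <- fsp_auto_truncate(p, t, leak_bound)
    d <- fsp_propagate(p, N, seq(0, t, length.out = grid_points))
    size_atoms(d, t, p)
  })
  atoms <- do.call(rbind, lapply(parts, `[[`, "atoms"))
  structure(list(atoms = atoms[order(atoms$size), ], t = t,
                 leak = max(vapply(parts, `[[`, 0, "leak")),
                 params = params_base),
            class = "size_atom_set")
}

#' Size distribution under a distributed initial size
#'
#' The fixed-initial-size mixture is convolved with an initial-size
#' distribution by discretizing it into `n_nodes` equal-probability
#' quantile nodes (deterministic; converges weakly as `n_nodes` grows),
#' solving each node's division-count distribution, and merging the
#' probability-weighted atom sets. Atoms coinciding in size (relative
#' tolerance 1e-9, e.g. an initial size of `2*s0` one division ahead of
#' `s0`) are merged; their `source_s0` is then `NA`.
#'
#' @param spec An [initial_size_spec()].
#' @param n_nodes Number of quantile nodes, >= 1 (ignored for `"fixed"`
#'   and `"atoms"` specs, which carry their own nodes).
#' @param t Evaluation time, > 0.
#' @param params_base A [model_params()]; `s0` is replaced per node.
#' @param leak_bound,grid_points As in [envelope_atoms()].
#' @return A combined `size_atom_set` with merged atoms; total weight is
#'   `1 - leak` with `leak` the probability-weighted truncation deficit.
#' @export
initial_size_mixture <- function(spec, n_nodes, t, params_base,
                                 leak_bound = 1e-8, grid_points = 257L) {
  stopifnot(inherits(params_base, "crm_params"))
  if (!inherits(spec, "initial_size_spec"))
    stop("'spec' must be an initial_size_spec", call. = FALSE)
  nodes <- initial_size_nodes(spec, n_nodes)
  parts <- Map(function(s0, w) {
    p <- model_params(params_base$mu, params_base$k, s0,
                      params_base$lambda)
    N <- fsp_auto_truncate(p, t, leak_bound)
    d <- fsp_propagate(p, N, seq(0, t, length.out = grid_points))
    a <- size_atoms(d, t, p)
    a$atoms$weight <- a$atoms$weight * w
    list(atoms = a$atoms, leak = a$leak * w)
  }, nodes$s0, nodes$w)
  atoms <- do.call(rbind, lapply(parts, `[[`, "atoms"))
  atoms <- atoms[order(atoms$size), ]
  # merge atoms whose sizes coincide up to relative round-off
  grp <- cumsum(c(TRUE, diff(atoms$size) > 1e-9 * atoms$size[-1L]))
  merged <- do.call(rbind, lapply(split(atoms, grp), function(g) {
    data.frame(source_s0 = if (length(unique(g$source_s0)) == 1L)
                 g$source_s0[1L] else NA_real_,
               i = if (length(unique(g$i)) == 1L) g$i[1L] else NA_integer_,
               size = g$size[1L],
               size_over_s0 = g$size[1L] / params_base$s0,
               weight = sum(g$weight))
  }))
  rownames(merged) <- NULL
  structure(list(atoms = merged, t = t,
                 leak = sum(vapply(parts, `[[`, 0, "leak")),
                 params = params_base),
            class = "size_atom_set")
}
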