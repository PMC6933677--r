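#' Write a division-count distribution as long-format CSV
#'
#' Columns `(t, i, P, leak)`; a JSON sidecar `<path>.json` records the
#' parameters, truncation and solver tolerances.
#'
#' @param dist A `division_count_distribution`.
#' @param path Output CSV path.
#' @return The paths written (CSV, sidecar), invisibly.
#' @export
write_dist_csv <- function(dist, path) {
  stopifnot(inherits(dist, "division_count_distribution"))
  nt <- length(dist$t_grid)
  long <- data.frame(
    t = rep(dist$t_grid, times = dist$N + 1L),
    i = rep(0:dist$N, each = nt),
    P = pmax(as.vector(dist$P), 0),
    leak = rep(dist$leak, times = dist$N + 1L))
  utils::write.csv(long, path, row.names = FALSE)
  side <- paste0(path, ".json")
  jsonlite::write_json(
    list(params = list(mu = dist$params$mu, k = dist$params$k,
                       s0 = dist$params$s0, lambda = dist$params$lambda),
         N = dist$N, method = dist$method,
         ode_rtol = dist$rtol, ode_atol = dist$atol,
         final_leak = dist$leak[nt]),
    side, auto_unbox = TRUE, digits = NA)
  invisible(c(path, side))
}

#' Write a moment series as CSV
#' @param ms A `moment_series` (from [moments_n()] or [size_moments()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_moments_csv <- function(ms, path) {
  stopifnot(inherits(ms, "moment_series"))
  utils::write.csv(as.data.frame(ms), path, row.names = FALSE)
  invisible(path)
}

#' Write a size-atom set as CSV
#' @param aset A `size_atom_set`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_atoms_csv <- function(aset, path) {
  stopifnot(inherits(aset, "size_atom_set"))
  out <- cbind(t = aset$t, aset$atoms)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Write the pooled cycle table and per-time summary of an ensemble
#' @param ens An `ensemble_summary`.
#' @param cycles_path,summary_path Output CSV paths (either may be `NULL`
#'   to skip).
#' @return The paths written, invisibly.
#' @export
write_ensemble_csv <- function(ens, cycles_path = NULL,
                               summary_path = NULL) {
  stopifnot(inherits(ens, "ensemble_summary"))
  written <- character()
  if (!is.null(cycles_path)) {
    cyc <- ens$cycles
    if (is.null(cyc)) cyc <- data.frame(
      cell_id = integer(), generation = integer(), birth_time = numeric(),
      birth_size = numeric(), division_size = numeric(),
      added_size = numeric(), interdivision_time = numeric())
    utils::write.csv(cyc, cycles_path, row.names = FALSE)
    written <- c(written, cycles_path)
  }
  if (!is.null(summary_path)) {
    utils::write.csv(ens$summary, summary_path, row.names = FALSE)
    written <- c(written, summary_path)
  }
  invisible(written)
}

#' Write a run manifest
#'
#' Records the command, full configuration, seed and output file list so a
#' run can be reproduced exactly.
#'
#' @param dir Output directory.
#' @param command Command name.
#' @param config Configuration list (flat, JSON-serializable).
#' @param files Character vector of files the run wrote.
#' @return The manifest path, invisibly.
#' @export
write_manifest <- function(dir, command, config, files) {
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(
    list(command = command, config = config,
         package_version = as.character(utils::packageVersion("crmsize")),
         files = basename(files),
         started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
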