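# File formats: two-column reference curves, CSV tally export, JSON run
# configs, and the run archive written by simulate_run().

#' Read a two-column reference curve
#'
#' Reads delimited text with `#` comment lines: first column coordinate
#' (cm), second column value, optional third column sigma.
#'
#' @param path File path.
#' @return Tibble with columns `coordinate`, `value` and optionally
#'   `sigma`.
#' @export
read_curve <- function(path) {
  df <- utils::read.table(path, comment.char = "#", header = FALSE,
                          sep = ",")
  if (ncol(df) == 1)  # fall back to whitespace-delimited files
    df <- utils::read.table(path, comment.char = "#", header = FALSE)
  if (ncol(df) < 2) abort("curve file needs at least two columns")
  df <- df[!vapply(df[[2]], function(v) is.na(suppressWarnings(
    as.numeric(v))), TRUE), , drop = FALSE]
  df[] <- lapply(df, function(col) suppressWarnings(as.numeric(col)))
  names(df)[1:2] <- c("coordinate", "value")
  if (ncol(df) >= 3) names(df)[3] <- "sigma"
  as_tibble(df[, seq_len(min(3, ncol(df)))])
}

#' Write a 1D tally curve as CSV
#'
#' Writes `coordinate, value, sigma` columns with a `#` header carrying
#' the units.
#'
#' @param curve Tibble whose first column is the coordinate; `value` and
#'   optionally `sigma` columns are written.
#' @param path Output path.
#' @param units Named character vector of units for the header.
#' @export
write_curve <- function(curve, path,
                        units = c(coordinate = "cm", value = "a.u.")) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", paste(names(units), units, sep = " [",
                                collapse = "], "), "]"), con)
  coord <- names(curve)[1]
  df <- data.frame(coordinate = curve[[coord]], value = curve$value,
                   sigma = curve$sigma %||% NA_real_)
  utils::write.table(format(df, digits = 8), con, sep = ",",
                     row.names = FALSE, quote = FALSE)
}

#' Write a run configuration as JSON
#' @param config List with elements `beam`, `grid` (or `NULL`),
#'   `transport`, and optionally `tallies`.
#' @param path Output path.
#' @export
write_run_config <- function(config, path) {
  enc <- list(
    beam = unclass(config$beam),
    grid = if (!is.null(config$grid)) {
      g <- unclass(config$grid)
      g$material <- list(name = g$material$name,
                         density = g$material$density,
                         composition = as.list(g$material$composition))
      g$tray_material <- NULL
      g
    },
    transport = unclass(config$transport),
    tallies = if (!is.null(config$tallies)) unclass(config$tallies)
  )
  jsonlite::write_json(enc, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
}

#' Read and validate a run configuration
#'
#' Schema-validates before any compute: unknown keys are rejected, and the
#' constructors re-check all invariants.
#'
#' @param path JSON file written by [write_run_config()] (or by hand).
#' @return List with `beam`, `grid`, `transport`, `tallies` objects.
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  allowed <- c("beam", "grid", "transport", "tallies")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown))
    abort(paste("unknown config keys:", paste(unknown, collapse = ", ")))
  take <- function(x, fn) {
    ok <- names(formals(fn))
    bad <- setdiff(names(x), c(ok, "n_holes", "block_top_cm", "tray_top_cm",
                               "tray_material", "n_cyl", "np_bins", "p_e0",
                               "p_de", "ne_bins", "e_e0", "e_de"))
    if (length(bad))
      abort(paste("unknown config keys:", paste(bad, collapse = ", ")))
    do.call(fn, x[intersect(names(x), ok)])
  }
  grid <- NULL
  if (!is.null(cfg$grid) && length(cfg$grid)) {
    g <- cfg$grid
    mat <- material(unlist(g$material$composition), g$material$density,
                    name = g$material$name)
    g$material <- mat
    grid <- take(g, grid_spec)
  }
  list(beam = take(as.list(cfg$beam), beam_spec),
       grid = grid,
       transport = take(as.list(cfg$transport), transport_config),
       tallies = if (!is.null(cfg$tallies))
         take(as.list(cfg$tallies), tally_config) else tally_config())
}

#' Run a simulation from a config and archive the tallies
#'
#' Executes [run_simulation()] for a config (path or list) and writes a
#' plain-text archive under `out_dir`: CSV exports of every 1D tally
#' (units in the header), a JSON manifest (seed, histories, batches,
#' wall-clock, per-tally maximum relative uncertainty) and a human-readable
#' log.
#'
#' @param config Path to a JSON config or a list as returned by
#'   [read_run_config()].
#' @param out_dir Output directory (created if needed).
#' @return The `gridrt_run`, invisibly.
#' @export
simulate_run <- function(config, out_dir) {
  if (is.character(config)) config <- read_run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  run <- run_simulation(config$beam, config$grid, config$transport,
                        config$tallies %||% tally_config())
  wall <- as.numeric(difftime(Sys.time(), t0, units = "secs"))

  pdd <- pdd_curve(run)
  prof <- lateral_profile(run)
  write_curve(pdd, file.path(out_dir, "pdd.csv"),
              units = c(depth = "cm", value = "MeV/g/history"))
  write_curve(prof, file.path(out_dir, "profile.csv"),
              units = c(position = "cm", value = "MeV/g/history"))
  for (d in run$tally_config$spec_depths) {
    sp <- spectrum_table(run, "photon", depth = d)
    names(sp)[names(sp) == "fluence"] <- "value"
    write_curve(sp, file.path(out_dir, sprintf("photon_spectrum_%gcm.csv", d)),
                units = c(energy = "MeV", value = "1/cm^2/history"))
  }
  write_curve(dplyr::rename(in_air_fluence(run), coordinate = "tag"),
              file.path(out_dir, "in_air_fluence.csv"),
              units = c(tag = "", value = "1/cm^2/history"))

  rel <- function(cv) {
    ok <- cv$value > 0
    if (!any(ok)) return(NA_real_)
    max(cv$sigma[ok] / cv$value[ok])
  }
  manifest <- list(
    status = "complete",
    seed = config$transport$seed,
    n_histories = run$n_histories, n_batches = run$n_batches,
    wall_clock_s = wall,
    max_relative_sigma = list(pdd = rel(pdd), profile = rel(prof)),
    config_hash = sum(utf8ToInt(jsonlite::toJSON(
      unclass(config$transport), auto_unbox = TRUE))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(sprintf(
    "gridrt run: %g histories, %d batches, seed %s, %.1f s wall clock",
    run$n_histories, run$n_batches, config$transport$seed, wall),
    file.path(out_dir, "log.txt"))
  invisible(run)
}
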