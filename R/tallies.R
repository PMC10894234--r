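# Tally extraction: tag-resolved curves and spectra with batch-based
# standard errors, plus the per-MU normalization.

MEVG_TO_CGY <- 1.602176634e-8  # 1 MeV/g in cGy

TAG_LEVELS <- c("primary", "scattered", "total")

tag_slice <- function(arr, tag) {
  tag <- match.arg(tag, TAG_LEVELS)
  switch(tag,
         primary = arr[, 1, , drop = FALSE],
         scattered = arr[, 2, , drop = FALSE],
         total = arr[, 1, , drop = FALSE] + arr[, 2, , drop = FALSE])
}

# value and batch standard error per history from [bins x 1 x B] totals
batch_stats <- function(slice, n_per_batch) {
  v <- slice[, 1, , drop = TRUE]
  if (is.null(dim(v))) v <- matrix(v, nrow = 1)
  v <- v / n_per_batch
  B <- ncol(v)
  tibble(value = rowMeans(v),
         sigma = apply(v, 1, stats::sd) / sqrt(B))
}

new_curve <- function(df, kind, meta = list()) {
  attr(df, "kind") <- kind
  attr(df, "meta") <- meta
  class(df) <- c("gridrt_curve", class(df))
  df
}

#' Central-axis depth-dose curve
#'
#' Extracts the cylindrical-mesh dose tally as a depth curve (per source
#' history, MeV/g) with batch standard errors.
#'
#' @param run A [run_simulation()] result.
#' @param tag `"total"`, `"primary"` or `"scattered"`.
#' @param estimator `"track"` (forced-collision track-length dose estimator
#'   with CSDA electron transport, the low-variance default), `"kerma"`
#'   (track-length collision kerma, no electron transport, so no build-up)
#'   or `"deposit"` (fully analog electron energy deposition).
#' @param attribution For the track/deposit estimators: `"parent"`
#'   attributes a deposit to the tag the photon carried when it set the
#'   electron in motion; `"post_interaction"` uses the tag after the
#'   collision.
#' @return A tibble of class `gridrt_curve` with columns `depth` (cm, bin
#'   centers), `value`, `sigma`.
#' @export
pdd_curve <- function(run, tag = "total",
                      estimator = c("track", "deposit", "kerma"),
                      attribution = c("parent", "post_interaction")) {
  stopifnot(inherits(run, "gridrt_run"))
  estimator <- match.arg(estimator)
  attribution <- match.arg(attribution)
  pre <- attribution == "parent"
  arr <- switch(estimator,
                kerma = run$tallies$cyl_kerma,
                track = if (pre) run$tallies$cyl_fdose_pre
                        else run$tallies$cyl_fdose_post,
                deposit = if (pre) run$tallies$cyl_edep_pre
                          else run$tallies$cyl_edep_post)
  st <- batch_stats(tag_slice(arr, tag), run$n_per_batch)
  tc <- run$tally_config
  depth <- (seq_len(tc$n_cyl) - 0.5) * tc$cyl_dz
  new_curve(tibble(depth = depth, value = st$value, sigma = st$sigma),
            "depth", list(estimator = estimator, tag = tag,
                          ssd = run$transport$ssd))
}

#' Lateral dose profile at the profile-mesh depth
#'
#' @inheritParams pdd_curve
#' @return A tibble of class `gridrt_curve` with columns `position` (cm),
#'   `value`, `sigma`.
#' @export
lateral_profile <- function(run, tag = "total",
                            estimator = c("kerma", "deposit")) {
  stopifnot(inherits(run, "gridrt_run"))
  estimator <- match.arg(estimator)
  arr <- switch(estimator, kerma = run$tallies$rect_kerma,
                deposit = run$tallies$rect_edep)
  st <- batch_stats(tag_slice(arr, tag), run$n_per_batch)
  tc <- run$tally_config
  pos <- seq(-tc$rect_half + tc$rect_dx / 2, tc$rect_half - tc$rect_dx / 2,
             by = tc$rect_dx)
  new_curve(tibble(position = pos, value = st$value, sigma = st$sigma),
            "lateral", list(estimator = estimator, tag = tag,
                            depth = tc$rect_depth))
}

#' Fluence spectrum in an axial voxel
#'
#' Track-length photon or electron fluence spectrum (per cm^2 per source
#' history) in the 4 mm radius x 2 mm height axial voxel at one of the
#' scored depths.
#'
#' @inheritParams pdd_curve
#' @param species `"photon"` (100 bins, 0.01-6.02 MeV) or `"electron"`
#'   (92 bins, 0.5-6.02 MeV).
#' @param depth One of the scored depths (default 1.5, 5 or 10 cm).
#' @return A tibble of class `gridrt_curve` with columns `energy` (bin
#'   midpoints, MeV), `fluence`, `sigma`.
#' @export
spectrum_table <- function(run, species = c("photon", "electron"),
                           depth = 1.5, tag = "total") {
  stopifnot(inherits(run, "gridrt_run"))
  species <- match.arg(species)
  tc <- run$tally_config
  kdi <- match(depth, tc$spec_depths)
  if (is.na(kdi)) abort(sprintf("depth must be one of %s",
                                paste(tc$spec_depths, collapse = ", ")))
  arr <- if (species == "photon") run$tallies$pspec[, , kdi, , drop = FALSE]
  else run$tallies$espec[, , kdi, , drop = FALSE]
  arr <- array(arr, dim = dim(arr)[c(1, 2, 4)])
  st <- batch_stats(tag_slice(arr, tag), run$n_per_batch)
  mids <- if (species == "photon")
    tc$p_e0 + (seq_len(tc$np_bins) - 0.5) * tc$p_de
  else tc$e_e0 + (seq_len(tc$ne_bins) - 0.5) * tc$e_de
  new_curve(tibble(energy = mids, fluence = st$value, sigma = st$sigma),
            "spectrum", list(species = species, depth = depth, tag = tag))
}

#' Total axial fluence at the scored depths
#'
#' Sums the photon fluence spectrum over energy bins at each scored depth,
#' yielding the depth-fluence points used by the percentage depth fluence.
#'
#' @inheritParams spectrum_table
#' @return A tibble of class `gridrt_curve` with columns `depth`, `value`
#'   (fluence per cm^2 per history), `sigma`.
#' @export
fluence_at_depths <- function(run, species = "photon", tag = "total") {
  stopifnot(inherits(run, "gridrt_run"))
  tc <- run$tally_config
  rows <- purrr::map_dfr(seq_along(tc$spec_depths), function(kdi) {
    arr <- if (species == "photon") run$tallies$pspec[, , kdi, , drop = FALSE]
    else run$tallies$espec[, , kdi, , drop = FALSE]
    arr <- array(arr, dim = dim(arr)[c(1, 2, 4)])
    sl <- tag_slice(arr, tag)
    tot <- apply(sl, 3, sum) / run$n_per_batch  # per-batch sums over bins
    tibble(depth = tc$spec_depths[kdi], value = mean(tot),
           sigma = stats::sd(tot) / sqrt(length(tot)))
  })
  new_curve(rows, "depth_fluence", list(species = species, tag = tag))
}

#' In-air fluence in the slab below the grid
#'
#' Track-length photon fluence (per cm^2 per history) in the 50 x 50 x
#' 0.1 cm^3 slab below the grid position, per tag and total.
#'
#' @param run A [run_simulation()] result.
#' @return Tibble with columns `tag`, `value`, `sigma`.
#' @export
in_air_fluence <- function(run) {
  stopifnot(inherits(run, "gridrt_run"))
  v <- run$tallies$inair / run$n_per_batch
  B <- ncol(v)
  tot <- colSums(v)
  tibble(tag = TAG_LEVELS,
         value = c(rowMeans(v), mean(tot)),
         sigma = c(apply(v, 1, stats::sd), stats::sd(tot)) / sqrt(B))
}

#' Dose in an axial voxel at a given depth
#'
#' Averages the cylindrical-mesh dose over the bins spanning a voxel of
#' height `voxel_h` centered at `depth` (the TPR scoring voxel uses 4 mm).
#'
#' @inheritParams pdd_curve
#' @param depth Depth in cm.
#' @param voxel_h Voxel height in cm (multiple of the mesh bin height).
#' @return A list with elements `value` and `sigma` (MeV/g per history).
#' @export
dose_at_depth <- function(run, depth, voxel_h = 0.4, tag = "total",
                          estimator = "kerma") {
  stopifnot(inherits(run, "gridrt_run"))
  crv <- pdd_curve(run, tag = tag, estimator = estimator)
  sel <- crv$depth > depth - voxel_h / 2 & crv$depth < depth + voxel_h / 2
  if (!any(sel)) abort("depth outside the scored mesh")
  k <- sum(sel)
  list(value = mean(crv$value[sel]),
       sigma = sqrt(sum(crv$sigma[sel]^2)) / k)
}

#' Calibrate histories-per-MU from a reference run
#'
#' Uses the convention that 1 MU delivers 1 cGy at the depth of maximum
#' dose for the open 10 x 10 cm^2 field at SSD 100.  The reference run must
#' be exactly that configuration.
#'
#' @param reference_run Open-field 10 x 10, SSD 100 [run_simulation()]
#'   result.
#' @return A list of class `gridrt_calibration`: `histories_per_mu`,
#'   `d_max_mm`, `dose_max` (MeV/g per history).
#' @export
mu_calibration <- function(reference_run) {
  stopifnot(inherits(reference_run, "gridrt_run"))
  if (!is.null(reference_run$grid))
    abort("calibration requires the open reference field")
  fit <- pdd_and_dmax(pdd_curve(reference_run, estimator = "track"))
  structure(list(histories_per_mu = 1 / (fit$max_value * MEVG_TO_CGY),
                 d_max_mm = fit$d_max_mm, dose_max = fit$max_value),
            class = "gridrt_calibration")
}

#' Normalize a tally curve to per-MU units
#'
#' Converts per-history tallies to per-MU: fluences to 1/cm^2/MU, doses
#' from MeV/g per history to cGy/MU.  By construction the calibration
#' reference dose at its depth of maximum maps to 1 cGy/MU.
#'
#' @param curve A `gridrt_curve` (or any tibble with `value`/`sigma` or
#'   `fluence`/`sigma` columns).
#' @param calibration A [mu_calibration()].
#' @param quantity `"fluence"` or `"dose"`.
#' @return The curve with values rescaled to per-MU units.
#' @export
per_mu_normalize <- function(curve, calibration,
                             quantity = c("fluence", "dose")) {
  if (!inherits(calibration, "gridrt_calibration"))
    abort("`calibration` must come from mu_calibration()")
  quantity <- match.arg(quantity)
  fac <- calibration$histories_per_mu *
    if (quantity == "dose") MEVG_TO_CGY else 1
  vc <- if ("value" %in% names(curve)) "value" else "fluence"
  curve[[vc]] <- curve[[vc]] * fac
  if ("sigma" %in% names(curve)) curve$sigma <- curve$sigma * fac
  curve
}

#' @export
glance.gridrt_run <- function(x, ...) {
  bk <- x$bookkeeping
  tibble(n_histories = x$n_histories, n_batches = x$n_batches,
         ssd = x$transport$ssd,
         field = paste(x$beam$field_cm, collapse = "x"),
         grid = if (is.null(x$grid)) "open" else x$grid$material$name,
         energy_in = sum(bk$e_in),
         deposited_fraction = sum(bk$e_dep) / sum(bk$e_in))
}

#' @export
tidy.gridrt_run <- function(x, ...) {
  bind_rows(
    mutate(pdd_curve(x, estimator = "kerma"), tally = "pdd",
           coordinate = .data$depth, .keep = "unused"),
    mutate(lateral_profile(x), tally = "profile",
           coordinate = .data$position, .keep = "unused")
  )[, c("tally", "coordinate", "value", "sigma")]
}
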