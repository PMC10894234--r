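# Focused 127-hole hexagonal grid collimator geometry.
#
# The holes are cones converging at the source, so a ray from the focus is
# either fully inside a hole (zero block path) or fully in the block.  Hole
# positions and diameters are specified at the isocenter plane; a point
# (x, y, z) is inside a hole iff its central projection onto the isocenter
# plane falls inside one of the 127 disks.

#' Specify the grid collimator
#'
#' The block carries 127 holes in a hexagonal lattice (a central hole plus
#' six rings), 1.0 cm hole diameter and 2.0 cm center-to-center pitch
#' projected to the isocenter, covering a maximum 25 x 25 cm^2 field.  The
#' block thickness and mounting distance are not part of the published grid
#' description; the defaults (7.6 cm thick block with its bottom face 65 cm
#' from the source, under a 0.6 cm PMMA tray) are stated assumptions and
#' are configurable.
#'
#' @param material Grid material: `"brass"`, `"cerrobend"`, or a
#'   [material()].
#' @param hole_diameter_cm Hole diameter at the isocenter plane (cm).
#' @param pitch_cm Center-to-center distance at the isocenter plane (cm).
#' @param n_rings Hexagonal rings around the central hole (6 gives 127).
#' @param block_bottom_cm,block_thickness_cm Axial placement of the block
#'   (cm from the source).
#' @param tray_thickness_cm PMMA tray thickness, mounted directly above the
#'   block.
#' @param max_field_cm Maximum field the grid can cover at the isocenter.
#' @param sad Source-to-isocenter distance (cm).
#' @param block_radius_cm Lateral (physical) radius of the block and tray
#'   disks; defaults to the projected maximum-field radius plus 2 cm.
#' @return An object of class `gridrt_grid`.
#' @export
grid_spec <- function(material = "brass",
                      hole_diameter_cm = 1.0, pitch_cm = 2.0, n_rings = 6,
                      block_bottom_cm = 65.0, block_thickness_cm = 7.6,
                      tray_thickness_cm = 0.6, max_field_cm = 25,
                      sad = 100, block_radius_cm = NULL) {
  if (is.character(material)) material <- gr_material(material)
  stopifnot(inherits(material, "gridrt_material"))
  if (hole_diameter_cm >= pitch_cm)
    abort("holes overlap: hole diameter must be smaller than the pitch")
  block_top <- block_bottom_cm - block_thickness_cm
  tray_top <- block_top - tray_thickness_cm
  if (tray_top <= 0 || block_bottom_cm >= sad)
    abort("grid block must sit between the source and the isocenter")
  if (is.null(block_radius_cm))
    block_radius_cm <- max_field_cm / 2 * block_bottom_cm / sad + 2
  structure(list(material = material,
                 block_radius_cm = block_radius_cm,
                 hole_diameter_cm = hole_diameter_cm,
                 pitch_cm = pitch_cm, n_rings = n_rings,
                 n_holes = 1 + 3 * n_rings * (n_rings + 1),
                 block_bottom_cm = block_bottom_cm,
                 block_thickness_cm = block_thickness_cm,
                 block_top_cm = block_top,
                 tray_thickness_cm = tray_thickness_cm,
                 tray_top_cm = tray_top,
                 tray_material = gr_material("pmma"),
                 max_field_cm = max_field_cm, sad = sad),
            class = "gridrt_grid")
}

#' @export
print.gridrt_grid <- function(x, ...) {
  cat(sprintf(
    "<gridrt_grid> %d focused holes (%.1f cm / %.1f cm pitch at iso), %s\n",
    x$n_holes, x$hole_diameter_cm, x$pitch_cm, x$material$name))
  invisible(x)
}

#' Hole centers at the isocenter plane
#'
#' @param spec A [grid_spec()].
#' @return Tibble with columns `x`, `y` (cm at the isocenter plane), one
#'   row per hole; the central hole is at the origin.
#' @export
hole_centers <- function(spec) {
  stopifnot(inherits(spec, "gridrt_grid"))
  n <- spec$n_rings
  qs <- seq(-n, n)
  grid <- expand.grid(q = qs, r = qs)
  ring <- (abs(grid$q) + abs(grid$r) + abs(grid$q + grid$r)) / 2
  grid <- grid[ring <= n, ]
  p <- spec$pitch_cm
  tibble(x = p * (grid$q + 0.5 * grid$r),
         y = p * (sqrt(3) / 2) * grid$r)
}

#' Material path length of a ray through the grid block and tray
#'
#' Computes, for each downstream-directed ray, the length of grid material
#' and of tray material traversed.  Rays through a focused hole cone see
#' zero block material; rays through the solid block see the full slab
#' chord; edge-crossing rays see the exact partial chord (the hole-cone
#' crossings reduce to a quadratic in 1/z and are solved analytically).
#'
#' @param origin Numeric matrix (n x 3) or length-3 vector of ray origins
#'   (cm, source at the origin, z down-beam).
#' @param direction Matching matrix/vector of ray directions (normalized
#'   internally).
#' @param spec A [grid_spec()].
#' @return Tibble with columns `block_cm` and `tray_cm`.
#' @export
path_length_in_block <- function(origin, direction, spec) {
  stopifnot(inherits(spec, "gridrt_grid"))
  if (is.null(dim(origin))) origin <- matrix(origin, nrow = 1)
  if (is.null(dim(direction))) direction <- matrix(direction, nrow = 1)
  nrm <- sqrt(rowSums(direction^2))
  direction <- direction / nrm
  if (any(direction[, 3] <= 0)) abort("rays must be directed downstream")
  centers <- hole_centers(spec)
  R <- spec$hole_diameter_cm / 2
  sad <- spec$sad
  z0 <- spec$block_top_cm; z1 <- spec$block_bottom_cm

  block <- numeric(nrow(origin))
  for (i in seq_len(nrow(origin))) {
    o <- origin[i, ]; d <- direction[i, ]
    z0i <- min(max(z0, o[3]), z1)  # the ray may start inside the block
    mx <- d[1] / d[3]; my <- d[2] / d[3]
    gx <- o[1] - o[3] * mx; gy <- o[2] - o[3] * my
    # scaled (isocenter-plane) coordinates s(z) = sad*m + sad*g/z
    sx <- function(z) sad * mx + sad * gx / z
    sy <- function(z) sad * my + sad * gy / z
    s0 <- c(sx(z0i), sy(z0i)); s1 <- c(sx(z1), sy(z1))
    mid <- (s0 + s1) / 2
    reach <- sqrt(sum((s1 - s0)^2)) / 2 + R + 1e-9
    cand <- which((centers$x - mid[1])^2 + (centers$y - mid[2])^2 <
                    (reach + 0)^2 + 1e-12)
    # z-intervals inside any hole cone
    inside <- matrix(numeric(0), ncol = 2)
    for (j in cand) {
      cx <- centers$x[j]; cy <- centers$y[j]
      ax <- sad * gx; bx <- sad * mx - cx
      ay <- sad * gy; by <- sad * my - cy
      A <- ax^2 + ay^2; B <- 2 * (ax * bx + ay * by)
      C <- bx^2 + by^2 - R^2
      if (A < 1e-18) { # focus ray: inside for all z or none
        if (C < 0) inside <- rbind(inside, c(z0i, z1))
        next
      }
      disc <- B^2 - 4 * A * C
      if (disc <= 0) next
      vs <- sort((-B + c(-1, 1) * sqrt(disc)) / (2 * A)) # v = 1/z roots
      # quadratic in v opens upward (A>0): inside hole for v in (v1, v2)
      vlo <- vs[1]; vhi <- vs[2]
      if (vhi <= 0) next
      zlo <- if (vhi > 0) 1 / vhi else Inf
      zhi <- if (vlo > 0) 1 / vlo else Inf
      lo <- max(z0i, zlo); hi <- min(z1, zhi)
      if (hi > lo) inside <- rbind(inside, c(lo, hi))
    }
    open_dz <- 0
    if (nrow(inside) > 0) {
      inside <- inside[order(inside[, 1]), , drop = FALSE]
      cur <- inside[1, ]
      for (j in seq_len(nrow(inside))[-1]) {
        if (inside[j, 1] <= cur[2]) cur[2] <- max(cur[2], inside[j, 2])
        else { open_dz <- open_dz + cur[2] - cur[1]; cur <- inside[j, ] }
      }
      open_dz <- open_dz + cur[2] - cur[1]
    }
    block[i] <- (z1 - z0i - open_dz) / d[3]
  }
  tray_lo <- pmax(spec$tray_top_cm, origin[, 3])
  tibble(block_cm = block,
         tray_cm = pmax(0, spec$block_top_cm - tray_lo) / direction[, 3])
}

#' Transmit a photon batch through the grid and tray
#'
#' In `"attenuate_only"` mode every photon's weight is multiplied by
#' `exp(-mu_block * L_block - mu_tray * L_tray)` along its exact ray path
#' and tags are left unchanged (the transmitted-uncollided beam stays
#' primary).  In `"attenuate_and_scatter"` mode interactions in the tray
#' and block are sampled explicitly (analog Monte Carlo with Woodcock
#' tracking); photons that interact anywhere are tagged `"scattered"`,
#' absorbed photons are dropped, and annihilation photons from pair events
#' in the block are emitted.
#'
#' @param batch A `gridrt_batch` tibble above the tray.
#' @param spec A [grid_spec()].
#' @param mode `"attenuate_only"` or `"attenuate_and_scatter"`.
#' @param seed Integer seed (scatter mode).
#' @param photon_cutoff Photon transport cutoff in MeV (scatter mode).
#' @return A `gridrt_batch` tibble just below the block's bottom face.
#' @export
transmit_through_grid <- function(batch, spec,
                                  mode = c("attenuate_and_scatter",
                                           "attenuate_only"),
                                  seed = 1, photon_cutoff = 0.01) {
  mode <- match.arg(mode)
  stopifnot(inherits(spec, "gridrt_grid"))
  m <- tibble_to_batch(batch)
  if (any(m[, "z"] >= spec$tray_top_cm))
    abort("batch must start above the tray")
  if (mode == "attenuate_only") {
    pl <- path_length_in_block(m[, 1:3], m[, 4:6], spec)
    mu_b <- mu_total(spec$material, m[, "energy"])$total
    mu_t <- mu_total(spec$tray_material, m[, "energy"])$total
    m[, "weight"] <- m[, "weight"] *
      exp(-mu_b * pl$block_cm - mu_t * pl$tray_cm)
    t <- (spec$block_bottom_cm + 1e-6 - m[, "z"]) / m[, "uz"]
    m[, "x"] <- m[, "x"] + t * m[, "ux"]
    m[, "y"] <- m[, "y"] + t * m[, "uy"]
    m[, "z"] <- spec$block_bottom_cm + 1e-6
    return(batch_to_tibble(m))
  }
  res <- cpp_grid_pass(m, grid_geom_list(spec, photon_cutoff),
                       grid_mats_list(spec), as.integer(seed), TRUE)
  batch_to_tibble(res$batch)
}


grid_geom_list <- function(spec, pcut = 0.01) {
  list(tray_z0 = spec$tray_top_cm, tray_z1 = spec$block_top_cm,
       block_z0 = spec$block_top_cm, block_z1 = spec$block_bottom_cm,
       has_block = TRUE,
       pitch = spec$pitch_cm, hole_r = spec$hole_diameter_cm / 2,
       sad = spec$sad, max_ring = as.integer(spec$n_rings),
       pcut = pcut, r_block = spec$block_radius_cm)
}

grid_mats_list <- function(spec) {
  list(block = fine_mu_table(spec$material),
       tray = fine_mu_table(spec$tray_material))
}
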