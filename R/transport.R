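# Run orchestration: batching, seeding, and the grid-pass / in-air /
# phantom-transport pipeline around the C++ core.

#' Transport configuration
#'
#' @param n_histories Total number of source photons.
#' @param n_batches Number of statistical batches (>= 10); batch spread
#'   yields the reported standard errors.
#' @param seed Integer master seed; per-batch streams are derived from it.
#' @param photon_cutoff,electron_cutoff Transport cutoffs in MeV (0.01 and
#'   0.5; photons/electrons below them deposit locally).
#' @param electron_step CSDA electron sub-step in cm (<= 0.1 cm,
#'   water-equivalent).
#' @param rr_threshold,rr_factor Russian-roulette weight threshold and
#'   survival factor for deeply attenuated photons.
#' @param ssd Source-to-surface distance of the water phantom (cm).
#' @param phantom_half,phantom_depth Phantom half-width and depth (cm);
#'   defaults give the 50 x 50 x 50 cm^3 phantom.
#' @return An object of class `gridrt_transport`.
#' @export
transport_config <- function(n_histories = 2e6, n_batches = 10, seed = 1,
                             photon_cutoff = 0.01, electron_cutoff = 0.5,
                             electron_step = 0.1,
                             rr_threshold = 1e-4, rr_factor = 10,
                             ssd = 100, phantom_half = 25,
                             phantom_depth = 50) {
  stopifnot(photon_cutoff > 0, electron_cutoff > photon_cutoff,
            electron_cutoff < 6.02, n_batches >= 10, n_histories >= n_batches,
            electron_step > 0, electron_step <= 0.1)
  structure(list(n_histories = n_histories, n_batches = n_batches,
                 seed = seed, photon_cutoff = photon_cutoff,
                 electron_cutoff = electron_cutoff,
                 electron_step = electron_step,
                 rr_threshold = rr_threshold, rr_factor = rr_factor,
                 ssd = ssd, phantom_half = phantom_half,
                 phantom_depth = phantom_depth),
            class = "gridrt_transport")
}

#' Tally configuration
#'
#' Defaults reproduce the standard scoring setup: a cylindrical central-axis
#' dose mesh (4 mm radius, 2 mm height voxels over 0-30 cm), a rectangular
#' profile mesh (0.5 x 0.5 x 0.1 cm^3 voxels at 10 cm depth), photon and
#' electron fluence spectra (100 bins on 0.01-6.02 MeV and 92 bins on
#' 0.5-6.02 MeV) in 4 mm radius x 2 mm height axial voxels at depths 1.5,
#' 5 and 10 cm, and an in-air 50 x 50 x 0.1 cm^3 fluence slab below the
#' grid.
#'
#' @param cyl_r,cyl_dz,cyl_depth Cylindrical mesh radius, voxel height and
#'   depth span (cm).
#' @param rect_depth,rect_dx,rect_dz,rect_half,rect_yhw Profile mesh depth,
#'   lateral voxel size, thickness, half-span, and half-width of the scored
#'   row (cm).
#' @param spec_depths,spec_r,spec_h Spectrum voxel depths, radius, height.
#' @param inair_z,inair_half,inair_dz In-air slab top position, half-width
#'   and thickness (cm).
#' @return An object of class `gridrt_tallycfg`.
#' @export
tally_config <- function(cyl_r = 0.4, cyl_dz = 0.2, cyl_depth = 30,
                         rect_depth = 10, rect_dx = 0.5, rect_dz = 0.1,
                         rect_half = 15, rect_yhw = 0.25,
                         spec_depths = c(1.5, 5, 10), spec_r = 0.4,
                         spec_h = 0.2,
                         inair_z = 65, inair_half = 25, inair_dz = 0.1) {
  structure(list(cyl_r = cyl_r, cyl_dz = cyl_dz, cyl_depth = cyl_depth,
                 n_cyl = as.integer(round(cyl_depth / cyl_dz)),
                 rect_depth = rect_depth, rect_dx = rect_dx,
                 rect_dz = rect_dz, rect_half = rect_half,
                 rect_yhw = rect_yhw,
                 spec_depths = spec_depths, spec_r = spec_r, spec_h = spec_h,
                 np_bins = 100L, p_e0 = PHOTON_EMIN,
                 p_de = (PHOTON_EMAX - PHOTON_EMIN) / 100,
                 ne_bins = 92L, e_e0 = ELECTRON_EMIN,
                 e_de = (ELECTRON_EMAX - ELECTRON_EMIN) / 92,
                 inair_z = inair_z, inair_half = inair_half,
                 inair_dz = inair_dz),
            class = "gridrt_tallycfg")
}

batch_seed <- function(seed, b, salt) {
  as.integer((as.numeric(seed) * 7919 + b * 104729 + salt) %% 2147483629)
}

#' Run a grid-therapy Monte Carlo simulation
#'
#' Generates the source batches, passes them through the grid collimator
#' and tray (if configured), scores the in-air fluence plane, transports
#' photons and CSDA secondary electrons through the water phantom, and
#' accumulates all tallies per statistical batch.  Identical configuration
#' and seed give bit-identical tallies.
#'
#' @param beam A [beam_spec()].
#' @param grid A [grid_spec()] or `NULL` for the open field (no block, no
#'   tray).
#' @param transport A [transport_config()].
#' @param tallies A [tally_config()].
#' @param phantom Logical; `FALSE` skips phantom transport (in-air runs).
#' @return An object of class `gridrt_run` holding tag-resolved tally
#'   arrays with a batch dimension plus the energy bookkeeping; use
#'   [pdd_curve()], [lateral_profile()], [spectrum_table()],
#'   [in_air_fluence()] and the analysis functions to extract results.
#' @export
run_simulation <- function(beam, grid = NULL,
                           transport = transport_config(),
                           tallies = tally_config(),
                           phantom = TRUE) {
  stopifnot(inherits(beam, "gridrt_beam"),
            inherits(transport, "gridrt_transport"),
            inherits(tallies, "gridrt_tallycfg"))
  B <- transport$n_batches
  nb <- ceiling(transport$n_histories / B)
  tc <- tallies

  geom <- list(ssd = transport$ssd, half = transport$phantom_half,
               depth = transport$phantom_depth,
               pcut = transport$photon_cutoff,
               ecut = transport$electron_cutoff,
               estep = transport$electron_step,
               rr_thresh = transport$rr_threshold,
               rr_factor = transport$rr_factor)
  mats <- list(water = fine_mu_table(gr_material("water")),
               electron = fine_e_table(gr_material("water")))
  tcfg <- list(n_cyl = tc$n_cyl, cyl_dz = tc$cyl_dz, cyl_r = tc$cyl_r,
               rect_depth = tc$rect_depth, rect_dz = tc$rect_dz,
               rect_dx = tc$rect_dx, rect_half = tc$rect_half,
               rect_yhw = tc$rect_yhw,
               spec_depths = tc$spec_depths, spec_r = tc$spec_r,
               spec_h = tc$spec_h,
               np_bins = tc$np_bins, p_e0 = tc$p_e0, p_de = tc$p_de,
               ne_bins = tc$ne_bins, e_e0 = tc$e_e0, e_de = tc$e_de)

  n_rect <- as.integer(round(2 * tc$rect_half / tc$rect_dx))
  nd <- length(tc$spec_depths)
  arr <- list(
    cyl_kerma = array(0, c(tc$n_cyl, 2, B)),
    cyl_edep_pre = array(0, c(tc$n_cyl, 2, B)),
    cyl_edep_post = array(0, c(tc$n_cyl, 2, B)),
    cyl_fdose_pre = array(0, c(tc$n_cyl, 2, B)),
    cyl_fdose_post = array(0, c(tc$n_cyl, 2, B)),
    rect_kerma = array(0, c(n_rect, 2, B)),
    rect_edep = array(0, c(n_rect, 2, B)),
    pspec = array(0, c(tc$np_bins, 2, nd, B)),
    espec = array(0, c(tc$ne_bins, 2, nd, B)),
    inair = array(0, c(2, B))
  )
  book <- vector("list", B)

  for (b in seq_len(B)) {
    set.seed(batch_seed(transport$seed, b, 1))
    m <- gen_beam_matrix(beam, nb)
    m[, "id"] <- m[, "id"] + (b - 1) * nb
    killed <- 0
    if (!is.null(grid)) {
      gp <- cpp_grid_pass(m, grid_geom_list(grid, transport$photon_cutoff),
                          grid_mats_list(grid),
                          batch_seed(transport$seed, b, 2), TRUE)
      m <- gp$batch
      killed <- gp$n_killed
    }
    arr$inair[, b] <- inair_score(m, tc)
    if (phantom) {
      res <- cpp_phantom_run(m, geom, mats, tcfg,
                             batch_seed(transport$seed, b, 3))
      arr$cyl_kerma[, , b] <- res$cyl_kerma
      arr$cyl_edep_pre[, , b] <- res$cyl_edep_pre
      arr$cyl_edep_post[, , b] <- res$cyl_edep_post
      arr$cyl_fdose_pre[, , b] <- res$cyl_fdose_pre
      arr$cyl_fdose_post[, , b] <- res$cyl_fdose_post
      arr$rect_kerma[, , b] <- res$rect_kerma
      arr$rect_edep[, , b] <- res$rect_edep
      arr$pspec[, , , b] <- aperm(res$pspec, c(2, 1, 3))
      arr$espec[, , , b] <- aperm(res$espec, c(2, 1, 3))
      book[[b]] <- tibble(batch = b, e_in = res$e_in, e_dep = res$e_dep,
                          e_escape = res$e_escape, rr_gain = res$rr_gain,
                          rr_loss = res$rr_loss,
                          out_of_mesh = res$out_of_mesh,
                          n_missed = res$n_missed, n_grid_killed = killed)
    } else {
      book[[b]] <- tibble(batch = b, e_in = sum(m[, 7] * m[, 8]),
                          e_dep = NA_real_, e_escape = NA_real_,
                          rr_gain = NA_real_, rr_loss = NA_real_,
                          out_of_mesh = NA_real_, n_missed = NA_real_,
                          n_grid_killed = killed)
    }
  }
  structure(list(tallies = arr, bookkeeping = bind_rows(book),
                 n_histories = B * nb, n_per_batch = nb, n_batches = B,
                 beam = beam, grid = grid, transport = transport,
                 tally_config = tc, phantom = phantom),
            class = "gridrt_run")
}

# in-air track-length fluence in the 50x50x0.1 slab, per tag (1/cm^2 summed)
inair_score <- function(m, tc) {
  uz <- m[, 6]
  ok <- uz > 1e-6
  t <- (tc$inair_z - m[, 3]) / uz
  x <- m[, 1] + t * m[, 4]
  y <- m[, 2] + t * m[, 5]
  ok <- ok & t > -1e-4 & abs(x) <= tc$inair_half & abs(y) <= tc$inair_half
  vol <- (2 * tc$inair_half)^2 * tc$inair_dz
  contrib <- m[, 8] * (tc$inair_dz / uz) / vol
  c(sum(contrib[ok & m[, 9] == 0]), sum(contrib[ok & m[, 9] == 1]))
}

#' @export
print.gridrt_run <- function(x, ...) {
  cat(sprintf(
    "<gridrt_run> %s field, %g histories in %d batches, SSD %g cm\n",
    if (is.null(x$grid)) "open" else x$grid$material$name,
    x$n_histories, x$n_batches, x$transport$ssd))
  invisible(x)
}
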