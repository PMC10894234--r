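test_that("hole lattice has 127 centers with the published spacing", {
  gs <- grid_spec()
  hc <- hole_centers(gs)
  expect_equal(nrow(hc), 127)
  expect_true(any(abs(hc$x) < 1e-12 & abs(hc$y) < 1e-12))
  d <- as.matrix(dist(hc))
  diag(d) <- Inf
  expect_equal(min(d), 2.0, tolerance = 1e-9)
  expect_error(grid_spec(hole_diameter_cm = 2.5), "overlap")
})

test_that("hole lattice is invariant under 60-degree rotation", {
  hc <- as.matrix(hole_centers(grid_spec()))
  th <- pi / 3
  rot <- hc %*% matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2)
  # every rotated center coincides with an original center
  d <- sqrt(outer(rot[, 1], hc[, 1], "-")^2 +
              outer(rot[, 2], hc[, 2], "-")^2)
  expect_lt(max(apply(d, 1, min)), 1e-9)
})

test_that("path lengths distinguish holes, septa and edges", {
  gs <- grid_spec()
  # focus ray through the central hole: zero block material
  pl <- path_length_in_block(c(0, 0, 0), c(0, 0, 1), gs)
  expect_equal(pl$block_cm, 0)
  expect_equal(pl$tray_cm, gs$tray_thickness_cm)
  # focus ray through the midpoint between two holes: full slab chord
  d <- c(1, 0, 100) / sqrt(1 + 100^2)
  pl2 <- path_length_in_block(c(0, 0, 0), d, gs)
  expect_equal(pl2$block_cm, gs$block_thickness_cm / d[3], tolerance = 1e-9)
})

test_that("open-area fraction matches the hexagonal-lattice value", {
  gs <- grid_spec()
  set.seed(9)
  n <- 4e4
  # focus rays uniform over one lattice cell at the isocenter plane
  xy <- cbind(runif(n, -1, 1), runif(n, -sqrt(3) / 2, sqrt(3) / 2))
  d <- cbind(xy / 100, 1)
  d <- d / sqrt(rowSums(d^2))
  pl <- path_length_in_block(matrix(0, n, 3), d, gs)
  open_frac <- mean(pl$block_cm == 0)
  p0 <- pi * 0.5^2 / (sqrt(3) / 2 * 2^2)
  expect_lt(abs(open_frac - p0), 3 * sqrt(p0 * (1 - p0) / n))
})

test_that("path lengths are additive when a ray is split", {
  gs <- grid_spec()
  set.seed(10)
  for (i in 1:20) {
    tgt <- runif(2, -4, 4)
    o <- c(runif(2, -0.05, 0.05), 0)
    d <- c(tgt - o[1:2], 100)
    d <- d / sqrt(sum(d^2))
    full <- path_length_in_block(o, d, gs)
    zmid <- runif(1, gs$block_top_cm, gs$block_bottom_cm)
    t1 <- (zmid - o[3]) / d[3]
    seg2 <- path_length_in_block(o + t1 * d, d, gs)
    # first segment evaluated via a block truncated at the split plane
    gs_trunc <- grid_spec(material = gs$material,
                          block_bottom_cm = zmid,
                          block_thickness_cm = zmid - gs$block_top_cm)
    seg1 <- path_length_in_block(o, d, gs_trunc)
    expect_equal(seg1$block_cm + seg2$block_cm, full$block_cm,
                 tolerance = 1e-9)
  }
})

test_that("attenuate-only transmission matches the closed form", {
  gs <- grid_spec()
  E <- 2.0
  # pencil through the fully blocked midpoint between holes
  n <- 2e4
  d <- c(1.1, 0, 100); d <- d / sqrt(sum(d^2))
  o <- d * (50 / d[3])
  batch <- tibble::tibble(x = rep(o[1], n), y = o[2], z = o[3],
                          ux = d[1], uy = d[2], uz = d[3],
                          energy = E, weight = 1, tag = "primary")
  class(batch) <- c("gridrt_batch", class(batch))
  ao <- transmit_through_grid(batch, gs, "attenuate_only")
  mu_b <- mu_total(gs$material, E)$total
  mu_t <- mu_total(gr_material("pmma"), E)$total
  expected <- exp(-(mu_b * gs$block_thickness_cm +
                      mu_t * gs$tray_thickness_cm) / d[3])
  expect_equal(mean(ao$weight), expected, tolerance = 1e-9)
  expect_true(all(ao$tag == "primary"))

  # analog scatter mode: surviving-primary fraction agrees within 3 sigma
  as_ <- transmit_through_grid(batch, gs, "attenuate_and_scatter", seed = 11)
  n_primary <- sum(as_$tag == "primary")
  se <- sqrt(n * expected * (1 - expected))
  expect_lt(abs(n_primary - n * expected), 3 * se)
})

test_that("open-field transmit leaves the beam untouched except the tray", {
  gs <- grid_spec()
  sp <- beam_spec()
  b <- generate_beam(sp, 5000, seed = 12, z_plane = 40)
  ao <- transmit_through_grid(b, gs, "attenuate_only")
  # weights through holes are reduced only by the tray
  mu_t <- mu_total(gr_material("pmma"), b$energy)$total
  pl <- path_length_in_block(cbind(b$x, b$y, b$z), cbind(b$ux, b$uy, b$uz),
                             gs)
  hole <- pl$block_cm == 0
  expect_gt(mean(hole), 0.15)
  expect_equal(ao$weight[hole], exp(-mu_t[hole] * pl$tray_cm[hole]),
               tolerance = 1e-9)
})
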