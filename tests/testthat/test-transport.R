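test_that("energy is conserved in every batch", {
  run <- mini_open()
  bk <- run$bookkeeping
  resid <- abs(bk$e_in + bk$rr_gain - bk$rr_loss - bk$e_dep - bk$e_escape) /
    bk$e_in
  expect_lt(max(resid), 1e-6)
})

test_that("identical seeds give bit-identical tallies, new seeds differ", {
  cfg <- transport_config(n_histories = 3e4, seed = 77)
  r1 <- run_simulation(beam_spec(), NULL, cfg)
  r2 <- run_simulation(beam_spec(), NULL, cfg)
  expect_identical(r1$tallies, r2$tallies)
  r3 <- run_simulation(beam_spec(), NULL,
                       transport_config(n_histories = 3e4, seed = 78))
  expect_false(identical(r1$tallies, r3$tallies))
})

test_that("tags partition the fluence exactly", {
  run <- mini_brass()
  sp_p <- spectrum_table(run, "photon", 1.5, tag = "primary")
  sp_s <- spectrum_table(run, "photon", 1.5, tag = "scattered")
  sp_t <- spectrum_table(run, "photon", 1.5, tag = "total")
  expect_equal(sp_p$fluence + sp_s$fluence, sp_t$fluence, tolerance = 1e-12)
  expect_gt(sum(sp_p$fluence), 0)
  expect_gt(sum(sp_s$fluence), 0)
  # an open in-air batch is entirely primary
  ia <- in_air_fluence(mini_open())
  expect_equal(ia$value[ia$tag == "scattered"], 0)
})

test_that("uncollided axial fluence follows inverse square and exp(-mu d)", {
  run <- mini_open()
  prim <- fluence_at_depths(run, tag = "primary")
  w <- gr_material("water")
  ssd <- 100
  # oracle: analytic attenuation of the source spectrum, quadrature over
  # the same spectral density the beam samples from
  dens <- function(E) E^0.44 * exp(-0.75 * E)
  att <- function(d) {
    integrate(function(E) dens(E) * exp(-mu_total(w, E)$total * d),
              0.011, 6.02, subdivisions = 400)$value /
      integrate(dens, 0.011, 6.02)$value
  }
  for (pair in list(c(1, 2), c(1, 3))) {
    d1 <- prim$depth[pair[1]]; d2 <- prim$depth[pair[2]]
    expected <- (att(d2) / att(d1)) * ((ssd + d1) / (ssd + d2))^2
    obs <- prim$value[pair[2]] / prim$value[pair[1]]
    se <- obs * sqrt((prim$sigma[pair[1]] / prim$value[pair[1]])^2 +
                       (prim$sigma[pair[2]] / prim$value[pair[2]])^2)
    expect_lt(abs(obs - expected), 3 * se + 0.01 * expected)
  }
})

test_that("the open-field depth dose builds up to a sub-surface maximum", {
  crv <- pdd_curve(mini_open(), estimator = "track")
  imax <- which.max(crv$value)
  expect_gt(crv$depth[imax], 0.5)
  expect_lt(crv$depth[imax], 3)
  expect_gt(crv$value[imax], 2 * crv$value[1])
})

test_that("batch standard errors shrink as one over sqrt(histories)", {
  sizes <- c(2e4, 8e4, 3.2e5)
  sig <- vapply(seq_along(sizes), function(i) {
    run <- run_simulation(beam_spec(), NULL,
                          transport_config(n_histories = sizes[i],
                                           n_batches = 30, seed = 80 + i))
    dose_at_depth(run, 10, voxel_h = 2, estimator = "kerma")$sigma
  }, 0)
  fit <- lm(log(sig) ~ log(sizes))
  expect_lt(abs(coef(fit)[2] + 0.5), 0.15)
})

test_that("open-field lateral profile is symmetric about the axis", {
  prof <- lateral_profile(mini_open())
  n <- nrow(prof)
  left <- prof[n:1, ]
  sel <- prof$value > 0 & left$value > 0 & abs(prof$position) < 5
  z <- sum(prof$value[sel] - left$value[sel]) /
    sqrt(sum(prof$sigma[sel]^2 + left$sigma[sel]^2))
  expect_lt(abs(z), 3)
})

test_that("no tally returns negative values", {
  run <- mini_brass()
  expect_true(all(run$tallies$cyl_kerma >= 0))
  expect_true(all(run$tallies$cyl_fdose_pre >= 0))
  expect_true(all(run$tallies$rect_kerma >= 0))
  expect_true(all(run$tallies$pspec >= 0))
  expect_true(all(run$tallies$espec >= 0))
  expect_true(all(run$tallies$inair >= 0))
})
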