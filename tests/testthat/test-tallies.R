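test_that("in-air slab fluence is exact for a perpendicular beam", {
  tc <- tally_config()
  n <- 1000
  m <- cbind(x = runif(n, -20, 20), y = runif(n, -20, 20), z = 0,
             ux = 0, uy = 0, uz = 1, energy = 2, weight = 1, tag = 0)
  sc <- gridrt:::inair_score(m, tc)
  expect_equal(sum(sc), n / (50 * 50), tolerance = 1e-12)
  expect_equal(sc[2], 0)
})

test_that("spectra integrate to the fluence totals regardless of binning", {
  run <- mini_open()
  sp <- spectrum_table(run, "photon", 5, tag = "total")
  fl <- fluence_at_depths(run, tag = "total")
  expect_equal(sum(sp$fluence), fl$value[fl$depth == 5], tolerance = 1e-12)
})

test_that("per-MU normalization pins the reference dose to 1 cGy/MU", {
  run <- mini_open()
  cal <- mu_calibration(run)
  expect_gt(cal$histories_per_mu, 0)
  crv <- per_mu_normalize(pdd_curve(run, estimator = "track"), cal,
                          quantity = "dose")
  fit <- pdd_and_dmax(crv)
  expect_equal(fit$max_value, 1.0, tolerance = 1e-9)
  expect_error(mu_calibration(mini_brass()), "open")
  expect_error(per_mu_normalize(crv, list()), "mu_calibration")
})

test_that("per-MU quantities are invariant under the history count", {
  r1 <- run_simulation(beam_spec(), NULL,
                       transport_config(n_histories = 2e5, seed = 90))
  r2 <- run_simulation(beam_spec(), NULL,
                       transport_config(n_histories = 6e5, seed = 91))
  f1 <- per_mu_normalize(fluence_at_depths(r1), mu_calibration(r1))
  f2 <- per_mu_normalize(fluence_at_depths(r2), mu_calibration(r2))
  expect_equal(f1$value, f2$value, tolerance = 0.1)
})

test_that("open-field axial fluence per MU has the expected magnitude", {
  run <- mini_open()
  cal <- mu_calibration(run)
  fl <- per_mu_normalize(fluence_at_depths(run, tag = "total"), cal)
  expect_equal(fl$value[fl$depth == 1.5] / 1e8, 16.98, tolerance = 0.15)
})

test_that("dose_at_depth averages the requested voxel", {
  run <- mini_open()
  crv <- pdd_curve(run, estimator = "kerma")
  d <- dose_at_depth(run, 10, voxel_h = 0.4)
  sel <- crv$depth > 9.8 & crv$depth < 10.2
  expect_equal(d$value, mean(crv$value[sel]), tolerance = 1e-12)
  expect_error(dose_at_depth(run, 45), "outside")
})

test_that("glance and tidy summarize a run", {
  g <- glance(mini_open())
  expect_equal(g$grid, "open")
  expect_gt(g$deposited_fraction, 0.5)
  td <- tidy(mini_open())
  expect_true(all(c("tally", "coordinate", "value", "sigma") %in% names(td)))
  expect_setequal(unique(td$tally), c("pdd", "profile"))
})
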