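test_that("parabolic d_max is exact on a symmetric toy curve", {
  fit <- pdd_and_dmax(triangle_curve())
  expect_equal(fit$d_max_mm, 15.0, tolerance = 1e-9)
  expect_equal(max(fit$curve$percent), 100, tolerance = 0.5)
})

test_that("pdd_and_dmax rejects degenerate curves", {
  crv <- triangle_curve()
  expect_error(pdd_and_dmax(crv[1:5, ]), "at least 10")
  mono <- tibble::tibble(depth = seq(0.1, 3, by = 0.2),
                         value = seq(10, 1, length.out = 15))
  expect_error(pdd_and_dmax(mono), "boundary")
})

test_that("output factor is a guarded ratio", {
  expect_equal(output_factor(5, 5)$value, 1)
  of <- output_factor(list(value = 4, sigma = 0.2),
                      list(value = 5, sigma = 0.1))
  expect_equal(of$value, 0.8)
  expect_equal(of$sigma, 0.8 * sqrt((0.2 / 4)^2 + (0.1 / 5)^2))
  expect_error(output_factor(1, 0), "zero")
})

test_that("tpr_20_10 validates its input geometries", {
  r80 <- run_simulation(beam_spec(), NULL,
                        transport_config(n_histories = 2e4, seed = 95,
                                         ssd = 80))
  r90 <- run_simulation(beam_spec(), NULL,
                        transport_config(n_histories = 2e4, seed = 96,
                                         ssd = 90))
  expect_error(tpr_20_10(r90, r80), "SSD")
  r90b <- run_simulation(beam_spec(field_cm = c(20, 20)), NULL,
                         transport_config(n_histories = 2e4, seed = 96,
                                          ssd = 90))
  expect_error(tpr_20_10(r80, r90b), "same beam")
  tpr <- tpr_20_10(r80, r90)
  expect_gt(tpr$value, 0)
  expect_lt(tpr$value, 1)
})

test_that("average energy is the fluence-weighted bin-midpoint mean", {
  one <- tibble::tibble(energy = c(1, 2, 3), fluence = c(0, 5, 0))
  expect_equal(average_energy(one), 2)
  two <- tibble::tibble(energy = c(1, 3), fluence = c(4, 4))
  expect_equal(average_energy(two), 2)
  # linearity: rescaling the spectrum leaves the mean unchanged
  sc <- two; sc$fluence <- sc$fluence * 7.3
  expect_equal(average_energy(sc), average_energy(two))
  zero <- tibble::tibble(energy = 1:3, fluence = rep(0, 3))
  expect_error(average_energy(zero), "zero")
})

test_that("percentage depth fluence is anchored at d_max", {
  # printed-style depth-fluence table as input
  fl <- tibble::tibble(depth = c(1.5, 5, 10), value = c(16.98, 15.41, 12.17))
  pdf <- pdf_depth_fluence(fl, d_max_mm = 15)
  expect_equal(pdf$pdf[1], 100)
  expect_equal(pdf$pdf[3], 100 * 12.17 / 16.98, tolerance = 1e-9)
  expect_error(pdf_depth_fluence(tibble::tibble(depth = 1:3, value = 0:2),
                                 10), "zero")
})

test_that("spatial fraction is exact on synthetic lattices", {
  x <- seq(-6, 6, by = 0.1)
  flat <- tibble::tibble(position = x, value = rep(2, length(x)))
  expect_equal(spatial_fraction(flat, pitch = 2)$value, 1.0)
  cosine <- tibble::tibble(position = x,
                           value = 1 + 0.6 * cos(2 * pi * x / 2))
  sf <- spatial_fraction(cosine, pitch = 2)
  expect_equal(sf$value, 0.4 / 1.6, tolerance = 1e-9)
  expect_error(spatial_fraction(flat[1:20, ], pitch = 20), "peaks")
})

test_that("spatial fraction lies in [0, 1] for non-negative profiles", {
  set.seed(42)
  x <- seq(-6, 6, by = 0.25)
  for (i in 1:10) {
    prof <- tibble::tibble(position = x,
                           value = abs(rnorm(length(x), 1, 0.5)))
    sf <- spatial_fraction(prof, pitch = 2, min_peak_frac = 0)
    expect_gte(sf$value, 0)
    expect_lte(sf$value, 1)
  }
})

test_that("dose components partition and normalize against the reference", {
  open <- mini_open()
  brass <- mini_brass()
  dc <- dose_components(brass, reference_run = open,
                        attribution = "post_interaction")
  expect_setequal(unique(dc$component), c("primary", "scattered", "total"))
  wide <- tidyr::pivot_wider(dc[, 1:3], names_from = "component",
                             values_from = "value")
  expect_equal(wide$primary + wide$scattered, wide$total, tolerance = 1e-9)
  # under post-interaction attribution almost all collision dose is
  # scattered-tagged
  expect_true(all(wide$scattered > wide$primary))
  # grid field has less scattered dose than the open field at equal depth
  dco <- dose_components(open, reference_run = open,
                         attribution = "post_interaction")
  wo <- tidyr::pivot_wider(dco[, 1:3], names_from = "component",
                           values_from = "value")
  expect_true(all(wo$scattered > wide$scattered))
})
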