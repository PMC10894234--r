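test_that("spectrum samples stay inside the truncated support", {
  sp <- beam_spec(alpha = 0.44, beta = 0.75)
  e <- sample_spectrum(sp, 2e4, seed = 1)
  expect_true(all(e > 0.01 & e <= 6.02))
  expect_error(beam_spec(alpha = -1.5), "normalizable")
  expect_error(beam_spec(beta = -0.1), "normalizable")
})

test_that("flat parameters give a uniform spectrum", {
  sp <- beam_spec(alpha = 0, beta = 0)
  e <- sample_spectrum(sp, 1e5, seed = 2)
  ks <- suppressWarnings(ks.test(e, "punif", 0.01, 6.02))
  expect_gt(ks$p.value, 0.01)
})

test_that("spectrum mean matches the truncated-density quadrature", {
  sp <- beam_spec(alpha = 0.8, beta = 1.1)
  e <- sample_spectrum(sp, 1e6, seed = 3)
  dens <- function(x) x^0.8 * exp(-1.1 * x)
  m_true <- integrate(function(x) x * dens(x), 0.01, 6.02)$value /
    integrate(dens, 0.01, 6.02)$value
  se <- sd(e) / sqrt(length(e))
  expect_lt(abs(mean(e) - m_true), 3 * se)
})

test_that("generated beams are collimated, primary, unit-norm and seeded", {
  sp <- beam_spec(field_cm = c(10, 10))
  b1 <- generate_beam(sp, 2e4, seed = 5)
  b2 <- generate_beam(sp, 2e4, seed = 5)
  expect_identical(b1, b2)
  expect_true(all(b1$tag == "primary"))
  expect_equal(sum(b1$weight), 2e4)
  expect_equal(b1$ux^2 + b1$uy^2 + b1$uz^2, rep(1, nrow(b1)),
               tolerance = 1e-12)
  # footprint at the isocenter plane: < 0.1% outside field + margin
  t <- (100 - b1$z) / b1$uz
  xi <- b1$x + t * b1$ux; yi <- b1$y + t * b1$uy
  frac_out <- mean(abs(xi) > 5.2 + 1e-9 | abs(yi) > 5.2 + 1e-9)
  expect_lt(frac_out, 0.001)
})

test_that("planar fluence follows the inverse-square law", {
  sp <- beam_spec(field_cm = c(10, 10), extra_focal_fraction = 0)
  b <- generate_beam(sp, 2e5, seed = 6, z_plane = 50)
  at_plane <- function(zp, r) {
    t <- (zp - b$z) / b$uz
    x <- b$x + t * b$ux; y <- b$y + t * b$uy
    sum(x^2 + y^2 < r^2)
  }
  n65 <- at_plane(65, 2)   # same physical disk radius at both planes
  n100 <- at_plane(100, 2)
  ratio <- n65 / n100
  se <- ratio * sqrt(1 / n65 + 1 / n100)
  expect_lt(abs(ratio - (100 / 65)^2), 3 * se)
})

test_that("beam tuning recovers engine-generated parameters", {
  truth <- c(alpha = 0.44, beta = 0.75)
  ref_run <- run_simulation(beam_spec(alpha = truth[1], beta = truth[2]),
                            NULL, transport_config(n_histories = 3e5,
                                                   seed = 70))
  ref <- pdd_and_dmax(pdd_curve(ref_run))$curve
  ref <- ref[ref$depth >= 0.5, c("depth", "percent")]
  grid <- tibble::tibble(alpha = c(0.44, 0.44, 2.0),
                         beta = c(0.75, 2.2, 0.2))
  fit <- tune_beam(ref, grid, n_histories = 1.5e5, seed = 71)
  expect_equal(fit$spec$alpha, 0.44)
  expect_equal(fit$spec$beta, 0.75)
  expect_equal(nrow(fit$diagnostics), 3)
  expect_true(all(fit$diagnostics$pass_rate >= 0 &
                    fit$diagnostics$pass_rate <= 100))
  expect_error(tune_beam(ref[1:3, ], grid), "at least 5")
  expect_error(tune_beam(ref, grid[0, ]), "empty")
})
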