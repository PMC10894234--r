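test_that("material constructor validates composition", {
  brass <- material(c(Zn = 0.37, Cu = 0.63), density = 8.49, name = "brass")
  expect_equal(unname(brass$composition), c(0.37, 0.63))
  expect_error(material(c(Xx = 1), 1), "Xx")
  expect_error(material(c(Cu = 0.5, Zn = 0.4), 8.4), "sum to 1")
  expect_error(material(c(Cu = 1), -2), "positive")
  w <- material(c(H = 0.112, O = 0.888), 1.0)
  expect_equal(sum(w$composition), 1)
})

test_that("attenuation lookups obey the mixture rule exactly", {
  es <- c(0.05, 0.3, 1.25, 4.8)
  a <- gr_material("brass")
  b <- gr_material("cerrobend")
  blend_comp <- c(0.4 * a$composition, 0.6 * b$composition)
  blend <- material(blend_comp, density = 1)
  mu_blend <- mu_total(blend, es)$total
  mu_mix <- 0.4 * mu_total(a, es)$total / a$density +
    0.6 * mu_total(b, es)$total / b$density
  expect_equal(mu_blend, mu_mix, tolerance = 1e-12)

  # single-component mixture is the element itself
  cu1 <- material(c(Cu = 1), 8.96)
  cu2 <- material(c(Cu = 1), 17.92)
  expect_equal(mu_total(cu2, es)$total, 2 * mu_total(cu1, es)$total,
               tolerance = 1e-12)
})

test_that("mu_total partials sum to total and errors outside the span", {
  w <- gr_material("water")
  m <- mu_total(w, c(0.02, 0.8, 2, 6))
  expect_equal(m$total,
               m$photoelectric + m$incoherent + m$coherent + m$pair,
               tolerance = 1e-12)
  expect_true(all(m$pair[m$energy <= 1.022] == 0))
  expect_error(mu_total(w, 0.005), "span")
  expect_error(mu_total(w, 7), "span")
})

test_that("water attenuation decreases monotonically over 0.1-2 MeV", {
  es <- seq(0.1, 2, by = 0.001)
  mu <- mu_total(gr_material("water"), es)$total
  expect_true(all(diff(mu) < 0))
})

test_that("brass attenuates less than cerrobend at 2 MeV", {
  expect_lt(mu_total(gr_material("brass"), 2)$total,
            mu_total(gr_material("cerrobend"), 2)$total)
})

test_that("sample_interaction matches the partial fractions", {
  w <- gr_material("water")
  # below the pair threshold no pair events can occur
  draws <- sample_interaction(w, 0.8, n = 2000, seed = 7)
  expect_false("pair" %in% draws)

  n <- 1e5
  draws <- sample_interaction(w, 2.0, n = n, seed = 8)
  p <- gridrt:::mass_mu_partials(w, 2.0)[1, ]
  p <- p / sum(p)
  for (proc in names(p)) {
    if (p[[proc]] < 1e-6) next
    obs <- mean(draws == proc)
    se <- sqrt(p[[proc]] * (1 - p[[proc]]) / n)
    expect_lt(abs(obs - p[[proc]]), 3 * se + 1e-12)
  }
})

test_that("Klein-Nishina samples respect kinematics and the KN mean", {
  E <- 1.25
  kn <- sample_klein_nishina(E, n = 1e6, seed = 3)
  k <- E / 0.51099895
  expect_true(all(kn$energy >= E / (1 + 2 * k) - 1e-12))
  expect_true(all(kn$energy <= E + 1e-12))
  # quadrature oracle over the analytic differential cross section
  eps_min <- 1 / (1 + 2 * k)
  f <- function(eps) {
    omc <- (1 / eps - 1) / k
    eps + 1 / eps - (1 - (1 - omc)^2)
  }
  mean_eps <- integrate(function(e) e * f(e), eps_min, 1)$value /
    integrate(f, eps_min, 1)$value
  se <- sd(kn$energy) / sqrt(nrow(kn))
  expect_lt(abs(mean(kn$energy) - E * mean_eps), 3 * se)
})

test_that("low-energy Compton approaches the symmetric Thomson limit", {
  kn <- sample_klein_nishina(0.001, n = 4e4, seed = 4)
  fwd <- mean(kn$theta < pi / 2)
  se <- sqrt(0.25 / nrow(kn))
  expect_lt(abs(fwd - 0.5), 3 * se + 0.01)
})

test_that("stopping power and residual range are consistent", {
  w <- gr_material("water")
  es <- seq(0.5, 6.02, length.out = 50)
  tab <- electron_stopping_and_range(w, es)
  expect_true(all(tab$stopping_power > 0))
  expect_true(all(diff(tab$csda_range) > 0))
  # independent fine-grid quadrature of 1/S reproduces the range within 1%
  eg <- exp(seq(log(0.5), log(6.02), length.out = 4000))
  sp <- electron_stopping_and_range(w, eg)$stopping_power
  inv <- 1 / sp
  cum <- c(0, cumsum(diff(eg) * (head(inv, -1) + tail(inv, -1)) / 2))
  oracle <- approx(eg, cum, es)$y
  expect_equal(tab$csda_range[-1], oracle[-1], tolerance = 0.01)
  # mass scaling: doubling the density halves the range in cm
  w2 <- material(w$composition, density = 2)
  tab2 <- electron_stopping_and_range(w2, es)
  expect_equal(tab2$csda_range, tab$csda_range / 2, tolerance = 1e-12)
  expect_error(electron_stopping_and_range(w, 0.3), "window")
})
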