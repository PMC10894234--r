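ramp <- function(x, s = 10) tibble::tibble(position = x, value = s * x)

test_that("identical curves give gamma zero everywhere", {
  x <- seq(0, 10, by = 0.2)
  ref <- ramp(x)
  g <- gamma_index_1d(ref, ref)
  expect_equal(max(tidy(g)$gamma[tidy(g)$evaluated]), 0, tolerance = 1e-9)
  expect_equal(glance(g)$pass_rate, 100)
})

test_that("a uniform +3% dose offset sits exactly on the pass boundary", {
  x <- seq(0, 10, by = 0.2)
  ref <- tibble::tibble(position = x, value = rep(50, length(x)))
  ev <- tibble::tibble(position = x, value = rep(50 * 1.03, length(x)))
  g <- gamma_index_1d(ref, ev, dose_tol_pct = 3, normalization = "global")
  gv <- tidy(g)$gamma[tidy(g)$evaluated]
  expect_equal(gv, rep(1, length(gv)), tolerance = 1e-6)
  expect_equal(glance(g)$pass_rate, 100)
})

test_that("a DTA-sized shift of a ramp gives the analytic gamma", {
  x <- seq(0, 10, by = 0.1)
  s <- 10
  ref <- ramp(x, s)
  shift <- 0.3  # cm = the DTA
  ev <- tibble::tibble(position = x, value = s * (x - shift))
  g <- gamma_index_1d(ref, ev, dose_tol_pct = 3, dta_mm = 3)
  delta <- 0.03 * max(ref$value)
  # analytic oracle: minimize (t/A)^2 + (s(t - shift)/delta)^2 over t
  A <- 0.3
  expected <- sqrt(optimize(function(t) (t / A)^2 +
                              (s * (t - shift) / delta)^2,
                            c(-1, 1))$objective)
  pts <- tidy(g)
  mid <- pts$evaluated & pts$position > 2 & pts$position < 9
  expect_equal(pts$gamma[mid], rep(expected, sum(mid)), tolerance = 1e-3)
})

test_that("gamma equals a brute-force minimization on random curves", {
  set.seed(13)
  x <- seq(0, 5, length.out = 20)
  for (rep in 1:3) {
    ref <- tibble::tibble(position = x, value = 50 + cumsum(rnorm(20, 0, 4)))
    ev <- tibble::tibble(position = x, value = ref$value +
                           rnorm(20, 0, 2))
    g <- gamma_index_1d(ref, ev, threshold_pct = 0)
    dta <- 0.3
    delta <- 0.03 * max(ref$value)
    brute <- vapply(seq_len(nrow(ev)), function(i) {
      xs <- seq(max(ev$position[i] - 3 * dta, min(x)),
                min(ev$position[i] + 3 * dta, max(x)), by = dta / 1000)
      rv <- approx(ref$position, ref$value, xs)$y
      min(sqrt(((xs - ev$position[i]) / dta)^2 +
                 ((ev$value[i] - rv) / delta)^2))
    }, 0)
    expect_equal(tidy(g)$gamma, brute, tolerance = 1e-3)
  }
})

test_that("loosening either criterion never lowers the pass rate", {
  set.seed(14)
  x <- seq(0, 5, length.out = 40)
  ref <- tibble::tibble(position = x, value = 60 + 10 * sin(x))
  ev <- tibble::tibble(position = x, value = ref$value + rnorm(40, 0, 2.5))
  base <- glance(gamma_index_1d(ref, ev, 2, 2))$pass_rate
  expect_gte(glance(gamma_index_1d(ref, ev, 3, 2))$pass_rate, base)
  expect_gte(glance(gamma_index_1d(ref, ev, 2, 3))$pass_rate, base)
  expect_gte(glance(gamma_index_1d(ref, ev, 4, 4))$pass_rate, base)
})

test_that("gamma is invariant under joint rescaling in global mode", {
  set.seed(15)
  x <- seq(0, 5, length.out = 30)
  ref <- tibble::tibble(position = x, value = 40 + cumsum(rnorm(30)))
  ev <- tibble::tibble(position = x, value = ref$value + rnorm(30))
  g1 <- tidy(gamma_index_1d(ref, ev))$gamma
  ref2 <- ref; ev2 <- ev
  ref2$value <- ref2$value * 37; ev2$value <- ev2$value * 37
  g2 <- tidy(gamma_index_1d(ref2, ev2))$gamma
  expect_equal(g1, g2, tolerance = 1e-9)
})

test_that("low-dose points are excluded and disjoint supports rejected", {
  x <- seq(0, 10, by = 0.5)
  ref <- tibble::tibble(position = x, value = c(rep(1, 10), rep(100, 11)))
  ev <- ref
  g <- gamma_index_1d(ref, ev, threshold_pct = 10)
  expect_gt(g$n_excluded, 0)
  far <- tibble::tibble(position = x + 100, value = ref$value)
  expect_error(gamma_index_1d(ref, far), "overlap")
})
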