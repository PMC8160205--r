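flat_profile <- function(value = 250, analyte = "oxygen") {
  microprofile(seq(0, 600, 100), rep(value, 7), analyte = analyte)
}

kinked_profile <- function(surface = 300, bulk = 250, delta = 500) {
  simulate_microprofile(bulk, delta, surface_value = surface)
}

test_that("profile constructor enforces the measurement conventions", {
  expect_error(microprofile(c(10, 35, 60, 85, 110), rep(1, 5)),
               class = "rl_error_input")          # must start at the surface
  expect_error(microprofile(c(0, 25, 25, 50, 75), rep(1, 5)),
               class = "rl_error_input")          # strictly increasing depths
  expect_error(microprofile(c(0, 25, 50), rep(1, 3)), class = "rl_error_input")
  expect_error(microprofile(seq(0, 100, 25), c(1, 2, -3, 4, 5)),
               class = "rl_error_input")          # negative oxygen
})

test_that("bulk estimation averages the stationary outer tail", {
  expect_equal(estimate_bulk(flat_profile())$bulk, 250)
  # linear 300 -> 250 over 0-500 um then flat to 1000 um
  p <- microprofile(c(seq(0, 500, 100), seq(600, 1000, 100)),
                    c(seq(300, 250, -10), rep(250, 5)))
  b <- estimate_bulk(p, n_outer = 3)
  expect_equal(b$bulk, 250)
  expect_true(b$stationary)
  # noisy tail: mean of generated tail values is the oracle
  set.seed(11)
  vals <- c(seq(300, 250, -10), 250 + rnorm(5, 0, 2))
  p2 <- microprofile(c(seq(0, 500, 100), seq(600, 1000, 100)), vals)
  b2 <- estimate_bulk(p2, n_outer = 3)
  expect_equal(b2$bulk, mean(tail(vals, 3)))
  expect_lt(abs(b2$bulk - 250), 2 * 2 / sqrt(3))
  expect_error(estimate_bulk(flat_profile(), n_outer = 1), class = "rl_error_input")
})

test_that("a sloped outer region raises the non-stationarity flag", {
  p <- microprofile(seq(0, 600, 100), seq(300, 240, -10))
  expect_warning(b <- estimate_bulk(p), class = "rl_warning_nonstationary")
  expect_false(b$stationary)
})

test_that("DBL thickness is the linear-gradient extrapolation to the bulk value", {
  d <- estimate_dbl(kinked_profile(), 250)
  expect_equal(d$thickness_um, 500)
  expect_equal(d$surface_value, 300)
  expect_equal(d$fit_r2, 1)
  expect_gte(d$n_fit, 3)
  # kink between grid points still recovered exactly (fit uses in-DBL points)
  d2 <- estimate_dbl(kinked_profile(delta = 487), 250)
  expect_equal(d2$thickness_um, 487)
  flat_fine <- microprofile(seq(0, 600, 25), rep(250, 25))
  expect_error(estimate_dbl(flat_fine, 250), class = "rl_error_degenerate")
  # extrapolation beyond the deepest point is refused
  shallow <- microprofile(seq(0, 100, 25), 300 - seq(0, 100, 25) * 0.1)
  expect_error(estimate_dbl(shallow, 250), class = "rl_error_out_of_range")
})

test_that("noisy profiles recover the imposed DBL thickness within 10%", {
  set.seed(42)
  est <- replicate(20, {
    p <- simulate_microprofile(250, 500, flux = 0.0724, noise_sd = 1)
    estimate_dbl(p, estimate_bulk(p))$thickness_um
  })
  expect_lt(abs(mean(est) / 500 - 1), 0.10)
})

test_that("Fick's law converts the gradient with the right units and sign", {
  d <- estimate_dbl(kinked_profile(), 250)
  f <- fick_flux(d)
  # hand conversion: 0.05 mol m-3 / 5e-4 m * 2.01e-9 m2 s-1 * 3600 / 1e4
  expect_equal(f$flux, 0.07236, tolerance = 1e-6)
  expect_gt(f$flux, 0)   # decreasing outward => efflux
  # doubling the gradient doubles J
  d2 <- estimate_dbl(kinked_profile(surface = 350), 250)
  f2 <- fick_flux(d2)
  expect_equal(f2$flux / f$flux, 2, tolerance = 1e-9)
  # dark profile: influx is negative
  dark <- estimate_dbl(kinked_profile(surface = 200), 250)
  expect_lt(fick_flux(dark)$flux, 0)
  # pH profiles have no Fick flux
  php <- simulate_microprofile(8.12, 400, surface_value = 8.5, analyte = "ph")
  dph <- estimate_dbl(php, 8.12)
  expect_error(fick_flux(dph), class = "rl_error_analyte")
})

test_that("larger DBL thickness at fixed endpoints means smaller flux magnitude", {
  f1 <- fick_flux(estimate_dbl(kinked_profile(delta = 300), 250))
  f2 <- fick_flux(estimate_dbl(kinked_profile(delta = 600), 250))
  expect_lt(abs(f2$flux), abs(f1$flux))
  expect_equal(abs(f1$flux) / abs(f2$flux), 2, tolerance = 1e-9)
})

test_that("round trip: generator-imposed delta and J are recovered to grid/2 and 1%", {
  for (delta in c(275, 410, 555)) {
    for (fl in c(0.05, -0.12)) {
      p <- simulate_microprofile(220, delta, flux = fl)
      d <- estimate_dbl(p, estimate_bulk(p))
      f <- fick_flux(d)
      expect_lt(abs(d$thickness_um - delta), 12.5)
      expect_lt(abs(f$flux / fl - 1), 0.01)
    }
  }
})

test_that("delta-pH is the signed surface-minus-bulk difference", {
  mk <- function(surf) simulate_microprofile(8.12, 400, surface_value = surf,
                                             analyte = "ph", species = "sp")
  expect_equal(delta_ph(mk(8.12), 8.12)$delta_ph, 0)
  expect_equal(delta_ph(mk(7.72), 8.12)$delta_ph, -0.40)
  expect_equal(delta_ph(mk(8.72), 8.12)$delta_ph, 0.60)
  # antisymmetry under swapping surface and bulk
  expect_equal(delta_ph(mk(7.9), 8.3)$delta_ph, -delta_ph(mk(8.3), 7.9)$delta_ph)
  o2 <- kinked_profile()
  expect_error(delta_ph(o2, 250), class = "rl_error_analyte")
})

test_that("diel surface-pH swing is light minus dark and checks identity", {
  mk <- function(surf, cond) simulate_microprofile(8.12, 400, surface_value = surf,
                                                   analyte = "ph", species = "sp",
                                                   location = "base", condition = cond)
  l <- delta_ph(mk(8.12 + 0.78, "light"), 8.12)
  d <- delta_ph(mk(8.12 - 0.40, "dark"), 8.12)
  expect_equal(diel_ph_range(l, d), 1.18)
  z <- delta_ph(mk(8.12, "light"), 8.12)
  expect_equal(diel_ph_range(z, z), 0)
  other <- delta_ph(simulate_microprofile(8.12, 400, surface_value = 8.3,
                                          analyte = "ph", species = "sp2",
                                          location = "base", condition = "dark"), 8.12)
  expect_error(diel_ph_range(l, other), class = "rl_error_mismatch")
})

test_that("consecutive traces average point-wise on the common grid", {
  p1 <- kinked_profile()
  p2 <- kinked_profile(surface = 310)
  avg <- average_profiles(p1, p2)
  expect_equal(avg$value[1], 305)
  expect_equal(avg$depth_um, p1$depth_um)
})

test_that("profile CSV dialect round-trips values and metadata", {
  p <- simulate_microprofile(210, 450, flux = 0.3, species = "L. crispatum",
                             location = "base", condition = "light")
  f <- tempfile(fileext = ".csv")
  write_microprofile(p, f)
  q <- read_microprofile(f)
  expect_equal(q$value, p$value)
  expect_identical(attr(q, "species"), "L. crispatum")
  expect_identical(attr(q, "location"), "base")
  expect_equal(attr(q, "bulk"), 210)
})

test_that("fit r-squared approaches 1 as profile noise vanishes", {
  set.seed(5)
  r2 <- sapply(c(1, 0.3, 0.02), function(s) {
    p <- simulate_microprofile(250, 500, flux = 0.0724, noise_sd = s)
    estimate_dbl(p, 250)$fit_r2
  })
  expect_true(all(diff(r2) > 0))
  expect_gt(r2[3], 0.999)
})
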