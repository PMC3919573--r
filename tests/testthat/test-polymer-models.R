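# Closed-form elasticity models and their numeric inversions.

test_that("Marko-Siggia force matches hand evaluation and limit behaviour", {
  expect_identical(wlc_force(0, 0.76), 0)
  # f = (kBT/Lp) * (1/(4(1-z)^2) - 1/4 + z) at z = 0.5, Lp = 0.76 nm
  expect_equal(wlc_force(0.5, 0.76), (4.114 / 0.76) * 1.25, tolerance = 1e-12)
  expect_gt(wlc_force(0.9, 0.76), wlc_force(0.5, 0.76))
  z <- seq(0, 0.999, length.out = 400)
  expect_true(all(diff(wlc_force(z, 1.0)) > 0))
  expect_error(wlc_force(1, 0.76), "\\[0, 1\\)")
  expect_error(wlc_force(-0.1, 0.76), "\\[0, 1\\)")
  expect_error(wlc_force(0.5, -1), "positive")
})

test_that("WLC inversion round-trips and obeys the high-force asymptote", {
  p <- wlc_params(Lp = 0.76, Lc = 1000)
  expect_identical(wlc_extension(0, p), 0)
  x <- wlc_extension(wlc_force(0.5, 0.76), p)
  expect_equal(x / p$Lc, 0.5, tolerance = 1e-10)
  # z -> 1 - sqrt(kBT / (4 f Lp)) at high force
  z40 <- wlc_extension(40, p) / p$Lc
  z_asym <- 1 - sqrt(4.114 / (4 * 40 * 0.76))
  expect_equal(z40, z_asym, tolerance = 0.03)
  expect_error(wlc_extension(-1, p), ">= 0")
})

test_that("low-force WLC response is entropic-spring-like", {
  Lp <- 0.8
  z <- seq(0.005, 0.05, by = 0.005)
  f <- wlc_force(z, Lp)
  expect_equal(f, (3 * 4.114 / (2 * Lp)) * z, tolerance = 0.05)
})

test_that("extensible WLC reduces to the inextensible limit and scales with 1/K", {
  f <- c(5, 10, 20, 40)
  p0 <- wlc_params(0.76, 1000)
  expect_equal(ewlc_extension(f, ewlc_params(0.76, 1000, 1e12)),
               wlc_extension(f, p0), tolerance = 1e-6)
  # multiplicative enthalpic factor is exact
  f8 <- wlc_force(0.8, 0.76)
  expect_equal(ewlc_extension(f8, ewlc_params(0.76, 1000, 800)),
               wlc_extension(f8, p0) * (1 + f8 / 800), tolerance = 1e-12)
  expect_gt(ewlc_extension(20, ewlc_params(0.76, 1000, 400)),
            ewlc_extension(20, ewlc_params(0.76, 1000, 800)))
  expect_error(ewlc_params(0.76, 1000, -5), "positive")
})

test_that("Ex-FJC matches its hand-evaluated value, series limit and bound", {
  p <- exfjc_params(LK = 1.91, Lc = 7857, K = 760)
  # b = 4.643, coth(b) - 1/b = 0.78479, x = 7857 * 0.78479 * 1.01316
  expect_equal(exfjc_extension(10, p), 6247.25, tolerance = 1e-5)
  expect_identical(exfjc_extension(0, p), 0)
  f_small <- 1e-6
  expect_equal(exfjc_extension(f_small, p),
               7857 * f_small * 1.91 / (3 * 4.114), tolerance = 1e-6)
  f <- c(0.1, 1, 5, 10, 20, 40)
  expect_true(all(exfjc_extension(f, p) < 7857 * (1 + f / 760)))
  expect_true(all(diff(exfjc_extension(f, p)) > 0))
})

test_that("thick chain is monotone, bounded, and reduces to the discrete FJC", {
  pt <- tc_params(delta = 0.83, l = 1.32, Lc = 8480)
  expect_identical(tc_extension(0, pt), 0)
  f <- seq(0.5, 40, length.out = 40)
  x <- tc_extension(f, pt)
  expect_true(all(diff(x) > 0))
  expect_true(all(x < pt$Lc))
  # constraint inactive when delta <= l/2: exactly the Langevin chain
  thin <- tc_params(delta = 0.3, l = 1.32, Lc = 8480)
  b <- f * 1.32 / 4.114
  expect_equal(tc_extension(f, thin), 8480 * (1 / tanh(b) - 1 / b),
               tolerance = 1e-12)
  expect_error(tc_params(-0.1, 1.32, 8480), "delta")
  expect_error(tc_params(0.8, -1, 8480), "delta >= 0, l > 0")
})

test_that("intrinsic bending stiffness stiffens the thick chain at low force", {
  pt <- tc_params(delta = 0.83, l = 1.32, Lc = 8480)
  x0 <- tc_extension(c(0.5, 2), pt)
  x1 <- tc_extension(c(0.5, 2), pt, Lp_local = 1)
  expect_true(all(x1 > x0))
})

test_that("all four models invert force-extension to high relative accuracy", {
  cond <- cond_na(100)
  f <- c(0.1, 0.5, 2, 10, 25, 40)
  models <- list(wlc_params(0.87, 9418.5),
                 ewlc_params(0.87, 9418.5, 800),
                 exfjc_params(1.55, 7857, 630),
                 tc_params(0.83, 1.32, 8480))
  for (p in models) {
    x <- model_extension(p, f, cond)
    expect_lt(max(abs(model_force(p, x, cond) - f) / f), 1e-8)
  }
})

test_that("matched low-force compliance ties the Kuhn length to 2 Lp", {
  Lp <- 0.8; Lc <- 1000
  f <- 1e-4
  slope_wlc <- wlc_extension(f, wlc_params(Lp, Lc)) / f
  slope_fjc <- exfjc_extension(f, exfjc_params(2 * Lp, Lc, 1e12)) / f
  expect_equal(slope_wlc, slope_fjc, tolerance = 0.01)
})

test_that("Debye length follows inverse-root ionic strength", {
  lam1M <- debye_length(conditions("monovalent", 1000, buffer_offset_mM = 0))
  expect_equal(lam1M, 0.304, tolerance = 0.005)
  lam <- function(c_mM) debye_length(conditions("monovalent", c_mM,
                                                buffer_offset_mM = 0))
  expect_equal(lam(400) / lam(100), 0.5, tolerance = 1e-10)
  expect_gt(lam(10), lam(1000))
  expect_error(debye_length(conditions("monovalent", 0, buffer_offset_mM = 0)),
               "ionic strength")
})
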