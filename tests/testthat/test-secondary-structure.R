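# Effective contour length, unpaired fraction, sigmoid fit, salt power law.

test_that("a pure WLC curve yields a constant effective contour length (n = 1)", {
  cond <- cond_na(1000)
  p <- wlc_params(0.76, 9555)
  fec <- model_fec(p, fmin = 0.4, fmax = 12, n = 400, cond = cond)
  lce <- effective_contour_length(fec, 0.76, cond = cond)
  frac <- unpaired_fraction(lce, 9555, 0.76)
  expect_true(all(abs(frac$n - 1) < 0.01))
  # halved extension halves the apparent contour length
  half <- pulling_curve(fec$position / 2, fec$force, sample_rate = 2)
  lce2 <- effective_contour_length(half, 0.76, cond = cond)
  expect_equal(lce2$Lc_eff, lce$Lc_eff / 2, tolerance = 1e-10)
})

test_that("grid forces outside the measured range are skipped with a warning", {
  cond <- cond_na(1000)
  fec <- model_fec(wlc_params(0.76, 9555), fmin = 1, fmax = 8, cond = cond)
  expect_warning(lce <- effective_contour_length(fec, 0.76, cond = cond),
                 "skipped")
  expect_true(all(lce$force >= 1 & lce$force <= 8))
  expect_error(effective_contour_length(fec, -1, cond = cond), "positive")
})

test_that("the sigmoid has its midpoint at fc and its floor near x0", {
  t6 <- tables$ss_sigmoid
  for (i in seq_len(nrow(t6))) {
    expect_equal(ss_sigmoid(t6$fc_pN[i], t6$fc_pN[i], t6$delta_pN[i], t6$x0[i]),
                 (1 + t6$x0[i]) / 2, tolerance = 1e-12)
  }
  # the zero-force value approaches x0 as the transition sharpens (fc >> delta)
  gap0 <- ss_sigmoid(0, 0.44, 2.09, 0.448) - 0.448
  gap1 <- ss_sigmoid(0, 5.322, 1.52, 0.029) - 0.029
  gap2 <- ss_sigmoid(0, 5.681, 1.43, 0.018) - 0.018
  expect_gt(gap0, gap1); expect_gt(gap1, gap2)
  expect_lt(gap2, 0.02)
})

test_that("unpaired fraction at 1-2 pN reaches 10-13% at the highest salt", {
  f <- seq(1, 2, by = 0.05)
  n <- ss_sigmoid(f, 5.322, 1.520, 0.029)
  expect_gte(max(n), 0.10); expect_lte(max(n), 0.13)
})

test_that("noiseless sigmoid round trips recover every published row exactly", {
  t6 <- tables$ss_sigmoid
  f <- seq(0.5, 10, by = 0.25)
  for (i in seq_len(nrow(t6))) {
    truth <- c(fc = t6$fc_pN[i], delta = t6$delta_pN[i], x0 = t6$x0[i])
    frac <- unpaired_fraction(
      data.frame(force = f, Lc_eff = ss_sigmoid(f, truth["fc"], truth["delta"],
                                                truth["x0"]) * 9555),
      9555)
    fit <- fit_ss_model(frac)
    expect_equal(unname(fit$estimate), unname(truth), tolerance = 1e-6)
    # fitted curve is nondecreasing in force
    nn <- ss_sigmoid(f, fit$estimate["fc"], fit$estimate["delta"],
                     fit$estimate["x0"])
    expect_true(all(diff(nn) >= 0))
  }
})

test_that("generator-modulated curves return the generating fraction", {
  cond <- cond_na(1000)
  ss <- list(fc = 5.322, delta = 1.520, x0 = 0.029)
  p <- wlc_params(0.76, 9555)
  fec <- bandwidth_filter(
    quick_noisy_fec(p, seed = 21, ss = ss, sd = 0, fmax = 40, cond = cond), 2)
  lce <- suppressWarnings(effective_contour_length(fec, 0.76, cond = cond))
  n_true <- ss_sigmoid(lce$force, ss$fc, ss$delta, ss$x0)
  expect_equal(lce$Lc_eff / 9555, n_true, tolerance = 0.01)
})

test_that("excluded-volume stiffening at low salt is flagged as n > 1", {
  cond <- cond_na(10)
  pt <- tc_params(0.83, 1.32, 8480)
  fec <- model_fec(pt, fmin = 0.5, fmax = 40, n = 600, cond = cond)
  fit <- fit_model(fec, "wlc", cond = cond)   # WLC from the 10-40 pN window
  lce <- effective_contour_length(fec, fit$estimate["Lp"], cond = cond)
  frac <- unpaired_fraction(lce, fit$estimate["Lc"])
  expect_true(any(frac$flagged))
  expect_true(all(frac$n[frac$flagged] > 1))
  expect_error(fit_ss_model(frac))
})

test_that("unphysical or undersized fraction curves are rejected", {
  f <- seq(1, 8, by = 1)
  decr <- unpaired_fraction(data.frame(force = f, Lc_eff = rev(f) * 100), 1000)
  expect_error(fit_ss_model(decr), "unphysical")
  few <- unpaired_fraction(data.frame(force = f[1:4], Lc_eff = f[1:4] * 100),
                           1000)
  expect_error(fit_ss_model(few), "at least 6")
})

test_that("zero-force fraction follows a salt power law with the default c*", {
  # exact recovery from noiseless power-law points
  cc <- c(100, 250, 500, 1000)
  x0 <- 3.0 * (cc - 65)^-0.8
  fit <- x0_vs_salt_powerlaw(cc, x0, "monovalent")
  expect_equal(fit$gamma, 0.8, tolerance = 1e-10)
  expect_equal(fit$scale, 3.0, tolerance = 1e-9)
  expect_equal(fit$c_star, 65)
  expect_equal(x0_vs_salt_powerlaw(c(1, 4, 10), 0.2 * c(1, 4, 10)^-0.5,
                                   "divalent")$c_star, 0)
  expect_warning(x0_vs_salt_powerlaw(c(50, 100, 250, 500), c(.5, .4, .3, .1),
                                     "monovalent"), "excluded")
  # noisy recovery stays near truth
  set.seed(77)
  x0n <- exp(log(x0) + rnorm(4, 0, 0.05))
  fitn <- x0_vs_salt_powerlaw(cc, x0n, "monovalent")
  expect_equal(fitn$gamma, 0.8, tolerance = 0.25)
})
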