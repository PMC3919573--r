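# Trace processing: trap correction, bandwidth reduction, windowing, fitting.

test_that("trap correction subtracts the bead displacement", {
  trap <- trap_model(0.07)
  fdc <- pulling_curve(c(1000, 1100), c(14, 0), kind = "FDC")
  fec <- fdc_to_fec(fdc, trap)
  expect_equal(fec$position, c(1000 - 200, 1100))
  expect_equal(fec$force, fdc$force)
  expect_identical(curve_kind(fec), "FEC")
  # positive force strictly decreases positions
  expect_true(all(fec$position[fdc$force > 0] < fdc$position[fdc$force > 0]))
  # exact inverse
  back <- fec_to_fdc(fec, trap)
  expect_equal(back$position, fdc$position)
  expect_error(fdc_to_fec(fec, trap), "must be an FDC")
  expect_error(trap_model(-1), "positive")
})

test_that("boxcar filtering decimates and suppresses white noise by sqrt(n)", {
  const <- pulling_curve(rep(5, 400), rep(2, 400), sample_rate = 200)
  filt <- bandwidth_filter(const, 2)
  expect_equal(nrow(filt), 4)
  expect_true(all(filt$force == 2) && all(filt$position == 5))
  expect_equal(sample_rate(filt), 2)

  set.seed(101)
  n <- 20000
  noisy <- pulling_curve(seq_len(n), rnorm(n, 10, 0.5), sample_rate = 200)
  ratio <- 0.5 / sd(bandwidth_filter(noisy, 2)$force)
  expect_gt(ratio, 8); expect_lt(ratio, 12)

  slow <- pulling_curve(1:10, 1:10, sample_rate = 3)
  expect_error(bandwidth_filter(slow, 2), "twice")
})

test_that("force windowing is inclusive and order-preserving", {
  f <- seq(0, 40, by = 0.5)
  curve <- pulling_curve(seq_along(f), f, sample_rate = 2)
  win <- window_by_force(curve, fit_window(10, 40))
  expect_equal(nrow(win), sum(f >= 10 & f <= 40))
  expect_equal(win$force, f[f >= 10 & f <= 40])
  inside <- window_by_force(win, fit_window(10, 40))
  expect_equal(as.data.frame(inside), as.data.frame(win))
  low <- pulling_curve(1:20, seq(0, 8, length.out = 20), sample_rate = 2)
  expect_error(window_by_force(low, fit_window(10, 40)), "no data in window")
})

test_that("noiseless WLC curves are recovered to near machine precision", {
  cond <- cond_na(100)
  p <- wlc_params(Lp = 0.87, Lc = 0.69 * 13650)
  fit <- fit_model(model_fec(p, cond = cond), "wlc", cond = cond)
  expect_equal(unname(fit$estimate["Lp"]), 0.87, tolerance = 1e-6)
  expect_equal(unname(fit$estimate["Lc"]), 0.69 * 13650, tolerance = 1e-6)
  expect_true(fit$converged)
  expect_lt(fit$rms, 1e-8)
})

test_that("noiseless extensible-model fits honour fixed parameters", {
  cond <- cond_na(10)
  pj <- exfjc_params(1.91, 7857, 760)
  fit <- fit_model(model_fec(pj, cond = cond), "exfjc", cond = cond,
                   fixed = list(Lc = 7857))
  expect_equal(unname(fit$estimate["LK"]), 1.91, tolerance = 1e-6)
  expect_equal(unname(fit$estimate["K"]), 760, tolerance = 1e-5)
  expect_named(fit$estimate, c("LK", "K"))
  expect_equal(unname(fit$fixed["Lc"]), 7857)
})

test_that("noisy seeded recovery matches generating WLC parameters", {
  cond <- cond_na(1000)
  p <- wlc_params(0.76, 0.70 * 13650)
  fec <- bandwidth_filter(quick_noisy_fec(p, seed = 42, cond = cond), 2)
  fit <- fit_model(fec, "wlc", cond = cond)
  expect_equal(unname(fit$estimate["Lp"]), 0.76, tolerance = 0.05)
  expect_equal(unname(fit$estimate["Lc"]) / 13650, 0.70, tolerance = 0.03)
  expect_true(all(fit$se > 0))
})

test_that("parameter recovery is unbiased over seeded replicates", {
  cond <- cond_na(1000)
  p <- wlc_params(0.76, 600)       # short molecule keeps replicates cheap
  errs <- vapply(1:24, function(s) {
    fec <- bandwidth_filter(quick_noisy_fec(p, seed = s, cond = cond), 2)
    unname(fit_model(fec, "wlc", cond = cond)$estimate["Lp"]) - 0.76
  }, numeric(1))
  expect_lt(abs(mean(errs)), 2 * sd(errs) / sqrt(length(errs)) + 1e-4)
})

test_that("fit is invariant to sample order and mild subsampling", {
  cond <- cond_na(1000)
  p <- wlc_params(0.76, 600)
  fec <- bandwidth_filter(quick_noisy_fec(p, seed = 5, cond = cond), 2)
  fit1 <- fit_model(fec, "wlc", cond = cond)
  set.seed(13)
  idx <- sample(nrow(fec))
  shuffled <- pulling_curve(fec$position[idx], fec$force[idx], sample_rate = 2)
  fit2 <- fit_model(shuffled, "wlc", cond = cond)
  expect_equal(fit1$estimate, fit2$estimate, tolerance = 1e-8)
  thin <- pulling_curve(fec$position[c(TRUE, FALSE)], fec$force[c(TRUE, FALSE)],
                        sample_rate = 1)
  fit3 <- fit_model(thin, "wlc", cond = cond)
  expect_equal(unname(fit3$estimate["Lp"]), unname(fit1$estimate["Lp"]),
               tolerance = 0.05)
})

test_that("adding extensibility barely moves the fit on WLC-like data", {
  # 10-40 pN curves consistent with the inextensible WLC: refitting with the
  # extensible variant drives K to effective inextensibility and changes
  # Lp by < 3% and Lc by < 1%
  cond <- cond_na(1000)
  fec <- bandwidth_filter(
    quick_noisy_fec(wlc_params(0.76, 9555), seed = 31, cond = cond), 2)
  fit_in <- fit_model(fec, "wlc", cond = cond)
  fit_ex <- fit_model(fec, "ewlc", cond = cond, start = list(K = 700))
  expect_gt(unname(fit_ex$estimate["K"]), 5000)
  expect_lt(abs(fit_in$estimate["Lp"] - fit_ex$estimate["Lp"]) /
              fit_in$estimate["Lp"], 0.03)
  expect_lt(abs(fit_in$estimate["Lc"] - fit_ex$estimate["Lc"]) /
              fit_in$estimate["Lc"], 0.01)
})

test_that("degenerate inputs are rejected", {
  flat <- pulling_curve(seq(100, 200, length.out = 50), rep(20, 50),
                        sample_rate = 2)
  expect_error(fit_model(flat, "wlc"), "degenerate")
  tiny <- pulling_curve(1:5 * 100, seq(12, 30, length.out = 5), sample_rate = 2)
  expect_error(fit_model(tiny, "wlc"), "at least 10")
})

test_that("replicate aggregation reports mean and molecule-to-molecule sd", {
  same <- replicate(3, fake_fit("wlc", c(Lp = 0.8, Lc = 9000)),
                    simplify = FALSE)
  agg <- aggregate_fits(same)
  expect_equal(agg$sd, c(0, 0))
  three <- lapply(c(0.75, 0.76, 0.77), function(v)
    fake_fit("wlc", c(Lp = v, Lc = 9000)))
  agg3 <- aggregate_fits(three)
  expect_equal(agg3$mean[agg3$parameter == "Lp"], 0.76)
  expect_equal(agg3$sd[agg3$parameter == "Lp"], 0.01)
  set.seed(9)
  vals <- rnorm(7, 1.5, 0.2)
  fits <- lapply(vals, function(v) fake_fit("exfjc", c(LK = v, K = 700)))
  agg7 <- aggregate_fits(fits)
  expect_equal(agg7$mean[agg7$parameter == "LK"], mean(vals))
  expect_equal(agg7$sd[agg7$parameter == "LK"], sd(vals))
  expect_error(aggregate_fits(c(three, fits[1])), "mixed model tags")
})
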