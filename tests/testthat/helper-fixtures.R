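# Shared fixtures: published parameter tables and fast synthetic curves.

tables <- salt_tables()

cond_na <- function(conc = 1000) conditions("monovalent", conc)
cond_mg <- function(conc = 10) conditions("divalent", conc)

# Noiseless FEC sampled directly on a force grid (no trap simulation).
model_fec <- function(params, fmin = 10, fmax = 40, n = 120, cond = NULL,
                      rate = 2) {
  f <- seq(fmin, fmax, length.out = n)
  pulling_curve(model_extension(params, f, cond), f, sample_rate = rate)
}

# Small, quick noisy trace through the full generator (short contour length
# keeps the trace a few thousand samples).
quick_noisy_fec <- function(params, seed, ss = NULL, sd = 0.5,
                            fmin = 0.5, fmax = 40, cond = NULL) {
  spec <- molecule_spec(params, ss = ss)
  generate_fec(spec, pulling_protocol(fmin = fmin, fmax = fmax),
               noise_model(sd, seed), cond)
}

# Minimal fec_fit stand-in for aggregation tests.
fake_fit <- function(model, est) {
  structure(list(model = model, estimate = est,
                 se = est * 0, fixed = NULL, rms = 0,
                 n_points = 10, window = fit_window(),
                 converged = TRUE, info = 1, message = "ok"),
            class = "fec_fit")
}

table1_series <- function() {
  t1 <- tables$wlc_nacl
  salt_series(t1$concentration_mM, t1$Lp_nm, t1$Lp_sd_nm, "monovalent")
}

table2_series <- function() {
  t2 <- tables$wlc_mgcl2
  salt_series(t2$concentration_mM, t2$Lp_nm, t2$Lp_sd_nm, "divalent")
}
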