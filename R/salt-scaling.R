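#' Per-salt series of fitted elastic parameters
#'
#' Holds one fitted parameter (persistence length, Kuhn length, ...) per
#' salt concentration, together with its dispersion and the effective
#' cation concentration (nominal + 9 mM buffer background for monovalent
#' salt; nominal for divalent salt).
#'
#' @param concentration_mM Nominal salt concentrations, mM.
#' @param value Fitted parameter values (nm or pN).
#' @param sd Optional dispersions (same units).
#' @param salt_type `"monovalent"` or `"divalent"`.
#' @param buffer_offset_mM Monovalent buffer background, mM.
#' @return A data frame of class `salt_series` with columns
#'   `concentration`, `c_eff`, `value`, `sd`.
#' @export
salt_series <- function(concentration_mM, value, sd = NULL,
                        salt_type = c("monovalent", "divalent"),
                        buffer_offset_mM = 9) {
  salt_type <- match.arg(salt_type)
  stopifnot(length(concentration_mM) == length(value))
  if (is.null(sd)) sd <- rep(NA_real_, length(value))
  c_eff <- effective_cation_concentration(concentration_mM, salt_type,
                                          buffer_offset_mM)
  structure(data.frame(concentration = concentration_mM, c_eff = c_eff,
                       value = value, sd = sd),
            salt_type = salt_type,
            class = c("salt_series", "data.frame"))
}

#' Persistence-length scaling with ionic strength
#'
#' Decomposes the persistence length into an intrinsic part and an
#' electrostatic part that decays with cation concentration:
#' `Lp(c) = Lp0 + A * c^(-nu/2)` with `c` the effective concentration in
#' mM. With the exponent held at `nu = 1` the electrostatic term is
#' proportional to the Debye screening length and the model is linear in
#' `c^(-1/2)`, so `fit_lp_scaling()` is an ordinary unweighted
#' least-squares line. `fit_lp_scaling_free_nu()` frees all three
#' parameters and uses Levenberg-Marquardt.
#'
#' Concentrations are used in mM throughout: the amplitude `A` is quoted
#' in nm mM^(nu/2) and its printed value depends on that convention.
#'
#' @param series A [salt_series()] of persistence lengths (nm).
#' @param nu Fixed exponent (default 1).
#' @return A list of class `scaling_fit`: `Lp0` (nm), `A`, `nu`, standard
#'   errors, and `r_squared`.
#' @export
fit_lp_scaling <- function(series, nu = 1) {
  stopifnot(inherits(series, "salt_series"))
  if (nrow(series) < 3) stop("fit_lp_scaling: need at least 3 entries")
  if (nu <= 0) stop("fit_lp_scaling: nu must be positive")
  xs <- series$c_eff^(-nu / 2)
  fit <- stats::lm(series$value ~ xs)
  cf <- stats::coef(fit); se <- sqrt(diag(stats::vcov(fit)))
  structure(list(Lp0 = unname(cf[1]), A = unname(cf[2]), nu = nu,
                 se = c(Lp0 = unname(se[1]), A = unname(se[2]), nu = NA_real_),
                 r_squared = summary(fit)$r.squared,
                 n_points = nrow(series)),
            class = "scaling_fit")
}

#' @rdname fit_lp_scaling
#' @param start Initial guesses for `(Lp0, A, nu)`.
#' @export
fit_lp_scaling_free_nu <- function(series, start = c(Lp0 = 0.7, A = 2, nu = 1)) {
  stopifnot(inherits(series, "salt_series"))
  if (nrow(series) < 4)
    stop("fit_lp_scaling_free_nu: need at least 4 entries")
  cc <- series$c_eff; y <- series$value
  obj <- minpack.lm::nls.lm(
    par = start,
    lower = c(Lp0 = 0, A = 0, nu = 1e-3),
    fn = function(p) p["Lp0"] + p["A"] * cc^(-p["nu"] / 2) - y,
    control = minpack.lm::nls.lm.control(maxiter = 500,
                                         ftol = 1e-14, ptol = 1e-14))
  if (!obj$info %in% 1:4)
    warning("fit_lp_scaling_free_nu: fit did not converge (", obj$message, ")")
  sm <- summary(obj)$coefficients
  ss_tot <- sum((y - mean(y))^2)
  structure(list(Lp0 = unname(obj$par["Lp0"]), A = unname(obj$par["A"]),
                 nu = unname(obj$par["nu"]),
                 se = sm[, "Std. Error"][names(obj$par)],
                 r_squared = 1 - obj$deviance / ss_tot,
                 n_points = nrow(series)),
            class = "scaling_fit")
}

#' @export
print.scaling_fit <- function(x, ...) {
  cat(sprintf("<scaling_fit> Lp = %.4g + %.4g * c^(-%.3g/2) nm (c in mM), R^2 = %.3f, %d points\n",
              x$Lp0, x$A, x$nu, x$r_squared, x$n_points))
  invisible(x)
}

#' Predict from a scaling fit
#'
#' @param object A `scaling_fit`.
#' @param c_eff_mM Effective cation concentrations, mM.
#' @param ... Unused.
#' @return Predicted persistence lengths, nm.
#' @export
predict.scaling_fit <- function(object, c_eff_mM, ...) {
  object$Lp0 + object$A * c_eff_mM^(-object$nu / 2)
}

#' Divalent/monovalent screening-equivalence factor
#'
#' How many times more efficient the divalent cation is at screening the
#' backbone charge: the factor `s` by which divalent concentrations must be
#' multiplied for the divalent persistence lengths to collapse onto the
#' monovalent Debye-scaling line (`nu = 1`). Found by minimising the squared
#' distance between the divalent points evaluated at `s * c` and the fitted
#' monovalent line; the analytic estimate `(A_mono / A_div)^2` from the two
#' separate `nu = 1` fits is reported alongside.
#'
#' @param series_na Monovalent [salt_series()] of persistence lengths.
#' @param series_mg Divalent [salt_series()] of persistence lengths.
#' @return A list: `factor` (least-squares collapse), `analytic`
#'   (`(A_na/A_mg)^2`), and the two `scaling_fit`s.
#' @export
mg_na_equivalence <- function(series_na, series_mg) {
  fit_na <- fit_lp_scaling(series_na, nu = 1)
  fit_mg <- fit_lp_scaling(series_mg, nu = 1)
  if (!is.finite(fit_na$A) || fit_na$A <= 0)
    stop("mg_na_equivalence: degenerate monovalent fit")
  cc <- series_mg$c_eff; y <- series_mg$value
  obj <- function(log10s)
    sum((y - predict(fit_na, 10^log10s * cc))^2)
  opt <- stats::optimize(obj, interval = c(-2, 6))
  list(factor = 10^opt$minimum,
       analytic = (fit_na$A / fit_mg$A)^2,
       fit_na = fit_na, fit_mg = fit_mg)
}

#' Kuhn-length trend with salt
#'
#' The Kuhn length decreases roughly logarithmically with cation
#' concentration; this fits `LK ~ log10(c_eff)` by ordinary least squares
#' and reports the slope (nm per decade). If a matching persistence-length
#' series is supplied, the semiflexible correspondence ratios
#' `LK / (2 Lp)` are reported per concentration (expected near 1).
#'
#' @param series_lk A [salt_series()] of Kuhn lengths (nm).
#' @param series_lp Optional matching [salt_series()] of persistence lengths.
#' @return A list: `slope` (nm/decade), `intercept`, and `ratio`
#'   (data frame of `concentration`, `LK_over_2Lp`) when `series_lp` is given.
#' @export
kuhn_trend <- function(series_lk, series_lp = NULL) {
  stopifnot(inherits(series_lk, "salt_series"))
  if (nrow(series_lk) < 3) stop("kuhn_trend: need at least 3 entries")
  fit <- stats::lm(series_lk$value ~ log10(series_lk$c_eff))
  out <- list(slope = unname(stats::coef(fit)[2]),
              intercept = unname(stats::coef(fit)[1]))
  if (!is.null(series_lp)) {
    stopifnot(inherits(series_lp, "salt_series"))
    m <- match(series_lk$concentration, series_lp$concentration)
    if (anyNA(m)) stop("kuhn_trend: concentration grids do not match")
    out$ratio <- data.frame(concentration = series_lk$concentration,
                            LK_over_2Lp = series_lk$value /
                              (2 * series_lp$value[m]))
  }
  out
}
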