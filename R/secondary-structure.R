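#' Force-dependent effective contour length
#'
#' At each force on a grid, the measured extension is interpolated from the
#' (bandwidth-filtered) FEC and divided by the relative extension the WLC
#' predicts at that force, using a persistence length fixed from the
#' 10-40 pN elastic fit: `Lc_eff(f) = x(f) / z_wlc(f; Lp)`. If the WLC with
#' a single contour length described the whole curve, `Lc_eff` would be
#' constant; secondary structure at low force shortens the apparent contour
#' length instead.
#'
#' Grid forces outside the measured force range are dropped with a warning;
#' zero force is excluded (the relative extension vanishes there).
#'
#' @param fec A [pulling_curve()] of kind FEC.
#' @param Lp_fixed Persistence length from the high-force fit, nm.
#' @param f_grid Force grid, pN (default 0.5-10 pN in 0.25 pN steps).
#' @param cond [conditions()] object.
#' @return A data frame with columns `force` and `Lc_eff` (nm).
#' @export
effective_contour_length <- function(fec, Lp_fixed,
                                     f_grid = seq(0.5, 10, by = 0.25),
                                     cond = NULL) {
  stopifnot(inherits(fec, "pulling_curve"))
  if (curve_kind(fec) != "FEC")
    stop("effective_contour_length: input must be an FEC")
  if (Lp_fixed <= 0) stop("effective_contour_length: Lp_fixed must be positive")
  f_grid <- f_grid[f_grid > 0]
  inside <- f_grid >= min(fec$force) & f_grid <= max(fec$force)
  if (!all(inside)) {
    warning("effective_contour_length: ", sum(!inside),
            " grid force(s) outside the measured range were skipped")
    f_grid <- f_grid[inside]
  }
  if (length(f_grid) == 0)
    stop("effective_contour_length: no grid forces inside the measured range")
  ord <- order(fec$force)
  x_at <- stats::approx(fec$force[ord], fec$position[ord], xout = f_grid,
                        ties = mean)$y
  z <- wlc_inverse_z(f_grid, Lp_fixed, cond)
  data.frame(force = f_grid, Lc_eff = x_at / z)
}

#' Unpaired-base fraction curve
#'
#' The fraction of bases not sequestered in secondary structure is the
#' ratio of the force-dependent effective contour length to the contour
#' length of the fully unpaired molecule (from the 10-40 pN fit):
#' `n(f) = Lc_eff(f) / Lc_max`. Values above 1 are physically impossible
#' for a paired/unpaired partition and signal excluded-volume stiffening
#' that the WLC cannot capture (low-salt regime); they are retained but
#' flagged, and excluded from sigmoid fitting.
#'
#' @param lc_eff Data frame from [effective_contour_length()] (columns
#'   `force`, `Lc_eff`).
#' @param Lc_max Reference contour length, nm.
#' @param Lp_fixed Persistence length used upstream, nm (stored for
#'   provenance).
#' @return A data frame of class `fraction_curve` with columns `force`,
#'   `n`, `flagged`.
#' @export
unpaired_fraction <- function(lc_eff, Lc_max, Lp_fixed = NA_real_) {
  stopifnot(is.data.frame(lc_eff), all(c("force", "Lc_eff") %in% names(lc_eff)))
  if (!is.numeric(Lc_max) || Lc_max <= 0)
    stop("unpaired_fraction: Lc_max must be positive")
  if (is.unsorted(lc_eff$force, strictly = TRUE))
    stop("unpaired_fraction: force grid must be strictly increasing")
  n <- lc_eff$Lc_eff / Lc_max
  structure(data.frame(force = lc_eff$force, n = n, flagged = n > 1),
            Lp_fixed = Lp_fixed, Lc_max = Lc_max,
            class = c("fraction_curve", "data.frame"))
}

#' Unpaired-fraction sigmoid
#'
#' Phenomenological description of the melting of non-specific secondary
#' structure with force:
#' `n(f) = x0 + (1 - x0) / (1 + exp(-(f - fc) / delta))`,
#' where `fc` is the critical force at which half of the nucleotides are
#' paired (`n(fc) = (1 + x0)/2`), `delta` the width of the transition and
#' `x0` the unpaired fraction extrapolated to zero force when the
#' transition is sharp (`fc >> delta`).
#'
#' @param f Force(s), pN.
#' @param fc Critical force, pN.
#' @param delta Transition width, pN.
#' @param x0 Zero-force unpaired fraction, in `[0, 1]`.
#' @return Fraction(s) `n(f)`.
#' @export
ss_sigmoid <- function(f, fc, delta, x0) {
  if (delta <= 0) stop("ss_sigmoid: delta must be positive")
  if (x0 < 0 || x0 > 1) stop("ss_sigmoid: x0 must lie in [0, 1]")
  x0 + (1 - x0) / (1 + exp(-(f - fc) / delta))
}

#' Fit the secondary-structure sigmoid to a fraction curve
#'
#' Bounded Levenberg-Marquardt fit of [ss_sigmoid()] to an unpaired
#' fraction curve. Flagged points (`n > 1`) are excluded; bounds are
#' `x0` in `[0, 1]`, `delta >= 0.05` pN, `fc` in `[0, 20]` pN; residuals
#' are unweighted.
#'
#' @param frac A [unpaired_fraction()] curve.
#' @param fit_range Optional force range `c(lo, hi)` to restrict the fit.
#' @return A list of class `ss_fit`: `estimate` and `se` for
#'   `fc`, `delta`, `x0`, plus residual RMS and point count.
#' @export
fit_ss_model <- function(frac, fit_range = NULL) {
  stopifnot(inherits(frac, "fraction_curve"))
  keep <- !frac$flagged
  if (!is.null(fit_range))
    keep <- keep & frac$force >= fit_range[1] & frac$force <= fit_range[2]
  f <- frac$force[keep]; n <- frac$n[keep]
  if (length(f) < 6) stop("fit_ss_model: need at least 6 usable grid points")
  if (any(n <= 0) || any(n > 1.05))
    stop("fit_ss_model: fractions must lie in (0, 1.05]")
  trend <- stats::coef(stats::lm(n ~ f))[2]
  if (trend < 0)
    stop("fit_ss_model: n(f) decreases with force - unphysical input")
  n_min <- min(n)
  half <- (1 + n_min) / 2
  fc0 <- f[which.min(abs(n - half))]
  p0 <- c(fc = max(min(fc0, 19), 0.1), delta = 1.5,
          x0 = min(max(n_min, 1e-4), 0.99))
  obj <- minpack.lm::nls.lm(
    par = p0,
    lower = c(fc = 0, delta = 0.05, x0 = 0),
    upper = c(fc = 20, delta = Inf, x0 = 1),
    fn = function(p) ss_sigmoid(f, p["fc"], p["delta"], p["x0"]) - n,
    control = minpack.lm::nls.lm.control(maxiter = 200,
                                         ftol = 1e-14, ptol = 1e-14))
  converged <- obj$info %in% 1:4
  if (!converged) warning("fit_ss_model: fit did not converge (", obj$message, ")")
  sm <- summary(obj)$coefficients
  structure(list(estimate = obj$par,
                 se = sm[, "Std. Error"][names(obj$par)],
                 rms = sqrt(obj$deviance / max(1, length(f) - 3)),
                 n_points = length(f),
                 converged = converged),
            class = "ss_fit")
}

#' @export
print.ss_fit <- function(x, ...) {
  cat(sprintf("<ss_fit> fc = %.3f +- %.3f pN, delta = %.3f +- %.3f pN, x0 = %.3f +- %.3f (%d points)%s\n",
              x$estimate["fc"], x$se["fc"], x$estimate["delta"], x$se["delta"],
              x$estimate["x0"], x$se["x0"], x$n_points,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  invisible(x)
}

#' Power law of the zero-force unpaired fraction vs salt
#'
#' Above a critical concentration `c*`, the zero-force unpaired fraction
#' decays as a power law, `x0 = scale * (c - c*)^(-gamma)`. The fit is an
#' ordinary least-squares line in log-log space, `log x0` against
#' `log(c - c*)`. Default critical concentrations: 65 mM for monovalent
#' salt (NaCl), 0 mM for divalent salt (MgCl2). Points with `c <= c*` are
#' excluded with a warning.
#'
#' @param concentration_mM Salt concentrations, mM.
#' @param x0 Zero-force unpaired fractions (positive).
#' @param salt_type `"monovalent"` or `"divalent"` (sets the default `c_star`).
#' @param c_star Critical concentration, mM; overrides the default.
#' @return A list of class `powerlaw_fit` with `gamma`, `scale`, `c_star`
#'   and the number of points used.
#' @export
x0_vs_salt_powerlaw <- function(concentration_mM, x0,
                                salt_type = c("monovalent", "divalent"),
                                c_star = NULL) {
  salt_type <- match.arg(salt_type)
  if (is.null(c_star))
    c_star <- if (salt_type == "monovalent") 65 else 0
  stopifnot(length(concentration_mM) == length(x0), all(x0 > 0))
  keep <- concentration_mM > c_star
  if (!all(keep))
    warning("x0_vs_salt_powerlaw: ", sum(!keep),
            " point(s) with c <= c* were excluded")
  cc <- concentration_mM[keep]; xx <- x0[keep]
  if (length(cc) < 3)
    stop("x0_vs_salt_powerlaw: need at least 3 points with c > c*")
  fit <- stats::lm(log(xx) ~ log(cc - c_star))
  structure(list(gamma = -unname(stats::coef(fit)[2]),
                 scale = exp(unname(stats::coef(fit)[1])),
                 c_star = c_star,
                 n_points = length(cc)),
            class = "powerlaw_fit")
}

#' @export
print.powerlaw_fit <- function(x, ...) {
  cat(sprintf("<powerlaw_fit> x0 = %.4g * (c - %g mM)^(-%.3f), %d points\n",
              x$scale, x$c_star, x$gamma, x$n_points))
  invisible(x)
}
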