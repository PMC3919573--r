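#' Fit an elasticity model to a force-extension curve
#'
#' Nonlinear least-squares fit of one of the four polymer models to an FEC.
#' The minimised residuals are in force: for each measured extension the
#' model force is computed (closed form for the WLC, monotone numeric
#' inversion for the extensible models, a force-grid interpolant for the
#' thick chain) and compared with the measured force. Optimisation uses
#' Levenberg-Marquardt ([minpack.lm::nls.lm()]) with positivity bounds;
#' per-parameter standard errors come from the linearised covariance
#' `(J'J)^-1 s^2` at the optimum.
#'
#' Parameters named in `fixed` are held at the given values (e.g.
#' `fixed = list(Lc = 7857)` to pin the Ex-FJC contour length to the
#' crystallographic value).
#'
#' @param curve A [pulling_curve()] of kind FEC.
#' @param model `"wlc"`, `"ewlc"`, `"exfjc"` or `"tc"`.
#' @param window A [fit_window()]; default 10-40 pN.
#' @param cond [conditions()] object.
#' @param fixed Named list of parameters to hold fixed.
#' @param start Named list overriding the default initial guesses.
#' @param maxiter Maximum Levenberg-Marquardt iterations.
#' @return An object of class `fec_fit`: estimates, standard errors, the
#'   residual RMS (pN), number of points, window and convergence info.
#' @examples
#' cond <- conditions("monovalent", 1000)
#' p <- wlc_params(Lp = 0.76, Lc = 9555)
#' f <- seq(10, 40, length.out = 60)
#' fec <- pulling_curve(model_extension(p, f, cond), f, sample_rate = 2)
#' fit_model(fec, "wlc", cond = cond)
#' @export
fit_model <- function(curve, model = c("wlc", "ewlc", "exfjc", "tc"),
                      window = fit_window(), cond = NULL,
                      fixed = list(), start = NULL, maxiter = 200) {
  model <- match.arg(model)
  stopifnot(inherits(curve, "pulling_curve"))
  if (curve_kind(curve) != "FEC") stop("fit_model: input must be an FEC")
  cond <- default_conditions(cond)
  win <- window_by_force(curve, window)
  x <- win$position; f <- win$force
  if (length(f) < 10) stop("fit_model: need at least 10 samples in the window")
  if (stats::sd(f) == 0) stop("fit_model: degenerate (constant-force) input")

  all_par <- .model_param_names(model)
  fixed <- fixed[names(fixed) %in% all_par]
  free <- setdiff(all_par, names(fixed))
  if (length(free) == 0) stop("fit_model: all parameters fixed")
  if (length(f) < length(free) + 1)
    stop("fit_model: fewer points than free parameters + 1")

  start_all <- .default_start(model, x)
  if (!is.null(start)) start_all[names(start)] <- unlist(start)
  start_all[names(fixed)] <- unlist(fixed)
  p0 <- unlist(start_all[free])
  lower <- .param_lower(model, x)[free]

  resid_fn <- .residual_builder(model, x, f, fixed, cond)
  obj <- minpack.lm::nls.lm(
    par = p0, lower = lower, fn = resid_fn,
    control = minpack.lm::nls.lm.control(maxiter = maxiter,
                                         ftol = 1e-12, ptol = 1e-12))
  converged <- obj$info %in% 1:4
  if (!converged)
    warning("fit_model: Levenberg-Marquardt did not converge (", obj$message, ")")
  n <- length(f); p <- length(free)
  sm <- summary(obj)$coefficients
  est <- obj$par; se <- sm[, "Std. Error"][names(est)]
  structure(list(model = model,
                 estimate = est,
                 se = se,
                 fixed = unlist(fixed),
                 rms = sqrt(obj$deviance / (n - p)),
                 n_points = n,
                 window = window,
                 converged = converged,
                 info = obj$info,
                 message = obj$message),
            class = "fec_fit")
}

#' @export
print.fec_fit <- function(x, ...) {
  cat(sprintf("<fec_fit %s> %d points in [%g, %g] pN, force RMS %.3g pN%s\n",
              toupper(x$model), x$n_points, x$window$fmin, x$window$fmax,
              x$rms, if (x$converged) "" else "  [NOT CONVERGED]"))
  tab <- data.frame(estimate = x$estimate, std.error = x$se)
  print(signif(tab, 5))
  if (length(x$fixed))
    cat("fixed:", paste(sprintf("%s = %g", names(x$fixed), x$fixed),
                        collapse = ", "), "\n")
  invisible(x)
}

#' Extract the fitted parameter object
#'
#' @param fit A `fec_fit`.
#' @return The corresponding [elastic_params] object (fixed + estimated).
#' @export
fitted_params <- function(fit) {
  stopifnot(inherits(fit, "fec_fit"))
  vals <- as.list(c(fit$estimate, fit$fixed))
  .make_elastic_params(fit$model, vals)
}

#' Aggregate replicate fits
#'
#' Per-parameter arithmetic mean and sample standard deviation over a list
#' of fits of the same model - the molecule-to-molecule dispersion that a
#' multi-curve experiment reports (distinct from the per-fit standard
#' errors, which measure within-curve uncertainty).
#'
#' @param results A list of `fec_fit` objects sharing one model tag.
#' @return A data frame with columns `parameter`, `mean`, `sd`, `n`.
#' @export
aggregate_fits <- function(results) {
  if (length(results) < 1) stop("aggregate_fits: need at least one result")
  stopifnot(all(vapply(results, inherits, logical(1), "fec_fit")))
  tags <- vapply(results, `[[`, character(1), "model")
  if (length(unique(tags)) != 1)
    stop("aggregate_fits: mixed model tags: ", paste(unique(tags), collapse = ", "))
  mat <- do.call(rbind, lapply(results, `[[`, "estimate"))
  data.frame(parameter = colnames(mat),
             mean = apply(mat, 2, mean),
             sd = if (nrow(mat) > 1) apply(mat, 2, stats::sd) else
               rep(0, ncol(mat)),
             n = nrow(mat),
             row.names = NULL)
}

## ---- internals -----------------------------------------------------------

.model_param_names <- function(model) {
  switch(model,
         wlc = c("Lp", "Lc"),
         ewlc = c("Lp", "Lc", "K"),
         exfjc = c("LK", "Lc", "K"),
         tc = c("delta", "l", "Lc"))
}

.make_elastic_params <- function(model, vals) {
  switch(model,
         wlc = wlc_params(vals$Lp, vals$Lc),
         ewlc = ewlc_params(vals$Lp, vals$Lc, vals$K),
         exfjc = exfjc_params(vals$LK, vals$Lc, vals$K),
         tc = tc_params(vals$delta, vals$l, vals$Lc))
}

.default_start <- function(model, x) {
  xm <- max(x)
  switch(model,
         wlc = list(Lp = 1, Lc = 1.05 * xm),
         ewlc = list(Lp = 1, Lc = 1.05 * xm, K = 700),
         exfjc = list(LK = 1.5, Lc = 1.2 * xm, K = 700),
         tc = list(delta = 0.8, l = 1.3, Lc = 1.1 * xm))
}

.param_lower <- function(model, x) {
  xm <- max(x)
  switch(model,
         wlc = c(Lp = 1e-3, Lc = xm * (1 + 1e-9)),
         ewlc = c(Lp = 1e-3, Lc = 1e-3, K = 1),
         exfjc = c(LK = 1e-3, Lc = 1e-3, K = 1),
         tc = c(delta = 0.05, l = 0.1, Lc = xm * (1 + 1e-9)))
}

# Residuals in force at the measured extensions.
.residual_builder <- function(model, x, f, fixed, cond) {
  force(fixed)
  if (model == "wlc") {
    function(par) {
      p <- c(as.list(par), as.list(fixed))
      z <- pmin(x / p$Lc, 1 - 1e-8)     # clamp: huge force repels Lc <= max(x)
      (cond$thermal_energy / p$Lp) * (1 / (4 * (1 - z)^2) - 0.25 + z) - f
    }
  } else if (model == "tc") {
    fgrid <- exp(seq(log(max(min(f) * 0.5, 0.05)), log(max(f) * 1.5),
                     length.out = 60))
    function(par) {
      p <- c(as.list(par), as.list(fixed))
      params <- .make_elastic_params("tc", p)
      xg <- model_extension(params, fgrid, cond, n_quad = 48)
      stats::approx(xg, fgrid, xout = pmin(x, max(xg)), rule = 2)$y - f
    }
  } else {
    function(par) {
      p <- c(as.list(par), as.list(fixed))
      params <- .make_elastic_params(model, p)
      .force_bisect(params, x, cond, f_max = max(f) * 20) - f
    }
  }
}
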