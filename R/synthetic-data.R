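#' Pulling protocol, molecule specification and noise model
#'
#' `pulling_protocol()` describes the instrument motion: the trap retracts
#' at constant speed (default 30 nm/s) while force and distance are sampled
#' at the acquisition rate (default 200 Hz), sweeping the force between
#' `fmin` and `fmax`. `molecule_spec()` describes the tether: number of
#' bases, its elastic model, optional secondary-structure sigmoid
#' parameters, and the trap. `noise_model()` sets the Gaussian force-noise
#' amplitude at the acquisition rate (default 0.5 pN, a typical
#' optical-tweezers magnitude) and the RNG seed.
#'
#' @param speed Pulling speed, nm/s.
#' @param rate Acquisition rate, Hz.
#' @param fmin,fmax Force range swept, pN.
#' @return `pulling_protocol()`: a classed list.
#' @export
pulling_protocol <- function(speed = 30, rate = 200, fmin = 0.5, fmax = 40) {
  stopifnot(speed > 0, rate > 0, fmin >= 0, fmax > fmin)
  structure(list(speed = speed, rate = rate, fmin = fmin, fmax = fmax),
            class = "pulling_protocol")
}

#' @rdname pulling_protocol
#' @param n_bases Number of nucleotides (default 13650).
#' @param elastic An [elastic_params] object (its `Lc` is the full contour
#'   length of the molecule).
#' @param ss Optional secondary-structure parameters: a list or named
#'   vector with `fc`, `delta`, `x0` (see [ss_sigmoid()]), or an `ss_fit`.
#' @param trap A [trap_model()].
#' @export
molecule_spec <- function(elastic, n_bases = 13650, ss = NULL,
                          trap = trap_model()) {
  stopifnot(inherits(elastic, "elastic_params"), n_bases > 0)
  if (inherits(ss, "ss_fit")) ss <- as.list(ss$estimate)
  if (!is.null(ss)) {
    ss <- as.list(unlist(ss)[c("fc", "delta", "x0")])
    if (anyNA(ss)) stop("molecule_spec: ss needs fc, delta and x0")
  }
  structure(list(n_bases = n_bases, elastic = elastic, ss = ss, trap = trap),
            class = "molecule_spec")
}

#' @rdname pulling_protocol
#' @param sd Force noise standard deviation at the acquisition rate, pN.
#' @param seed Integer RNG seed.
#' @export
noise_model <- function(sd = 0.5, seed = 1L) {
  stopifnot(sd >= 0)
  structure(list(sd = sd, seed = as.integer(seed)), class = "noise_model")
}

# evaluate code with a local, restored RNG state
.with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# composed model extension: contour length modulated by the unpaired
# fraction when secondary-structure parameters are present
.composed_extension <- function(spec, f, cond) {
  scale <- if (is.null(spec$ss)) 1
  else ss_sigmoid(f, spec$ss$fc, spec$ss$delta, spec$ss$x0)
  if (inherits(spec$elastic, "tc_params")) {
    # dense-grid monotone spline: the transfer operator is too costly to
    # evaluate at every sample
    fg <- seq(0, max(f) * 1.0001, length.out = 400)
    xg <- model_extension(spec$elastic, fg, cond)
    scale * stats::splinefun(fg, xg, method = "hyman")(f)
  } else {
    scale * model_extension(spec$elastic, f, cond)
  }
}

#' Generate a synthetic force-extension curve
#'
#' Emulates a quasi-static constant-velocity pull: the trap-molecule series
#' compliance converts the steady trap motion into a force ramp, which is
#' sampled at the acquisition rate and corrupted with Gaussian force noise.
#' Secondary structure, when specified, enters as a force-dependent
#' effective contour length `Lc * n(f)` with `n(f)` the [ss_sigmoid()] -
#' producing the characteristic low-force shoulder. With zero noise the
#' samples lie exactly on the composed model curve. Output is deterministic
#' given the seed; the global RNG state is left untouched.
#'
#' @param spec A [molecule_spec()].
#' @param protocol A [pulling_protocol()].
#' @param noise A [noise_model()].
#' @param cond [conditions()] object.
#' @return A [pulling_curve()] of kind FEC with a time column.
#' @examples
#' cond <- conditions("monovalent", 1000)
#' spec <- molecule_spec(wlc_params(0.76, 0.70 * 13650))
#' fec <- generate_fec(spec, pulling_protocol(), noise_model(seed = 7), cond)
#' @export
generate_fec <- function(spec, protocol = pulling_protocol(),
                         noise = noise_model(), cond = NULL) {
  stopifnot(inherits(spec, "molecule_spec"),
            inherits(protocol, "pulling_protocol"),
            inherits(noise, "noise_model"))
  cond <- default_conditions(cond)
  k <- spec$trap$stiffness
  fg <- seq(protocol$fmin, protocol$fmax, length.out = 4096)
  xg <- .composed_extension(spec, fg, cond)
  dg <- xg + fg / k                    # trap-pipette distance, monotone in f
  tg <- (dg - dg[1]) / protocol$speed  # time at which each force is reached
  t_i <- seq(0, tg[length(tg)], by = 1 / protocol$rate)
  f_i <- stats::approx(tg, fg, xout = t_i)$y
  x_i <- .composed_extension(spec, f_i, cond)   # exact model extension
  f_obs <- .with_seed(noise$seed,
                      f_i + stats::rnorm(length(f_i), sd = noise$sd))
  pulling_curve(x_i, f_obs, time = t_i, kind = "FEC",
                sample_rate = protocol$rate)
}

#' Generate a synthetic salt series
#'
#' Draws persistence lengths from the scaling law
#' `Lp(c) = Lp0 + A * c_eff^(-nu/2)` with additive Gaussian noise.
#'
#' @param law A `scaling_fit` or list with `Lp0`, `A`, `nu`.
#' @param concentrations_mM Nominal concentrations, mM.
#' @param sd Gaussian noise standard deviation, nm.
#' @param seed Integer RNG seed (`NULL` for the current RNG state).
#' @param salt_type `"monovalent"` or `"divalent"`.
#' @return A [salt_series()].
#' @export
generate_salt_series <- function(law, concentrations_mM, sd = 0, seed = NULL,
                                 salt_type = c("monovalent", "divalent")) {
  salt_type <- match.arg(salt_type)
  law <- as.list(law)
  stopifnot(all(c("Lp0", "A", "nu") %in% names(law)))
  c_eff <- effective_cation_concentration(concentrations_mM, salt_type)
  vals <- law$Lp0 + law$A * c_eff^(-law$nu / 2)
  vals <- .with_seed(seed, vals + stats::rnorm(length(vals), sd = sd))
  salt_series(concentrations_mM, vals, sd = rep(sd, length(vals)),
              salt_type = salt_type)
}
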