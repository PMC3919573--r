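#' Elasticity model parameter sets
#'
#' Constructors for the four force-extension models used to describe ssDNA:
#'
#' * `wlc_params(Lp, Lc)` - inextensible worm-like chain (Marko-Siggia
#'   interpolation), persistence length `Lp` and contour length `Lc`, nm.
#' * `ewlc_params(Lp, Lc, K)` - extensible WLC with stretch modulus `K` (pN),
#'   applied as the multiplicative enthalpic correction `x = x_wlc (1 + f/K)`.
#' * `exfjc_params(LK, Lc, K)` - extensible freely-jointed chain with Kuhn
#'   length `LK` (nm) and stretch modulus `K` (pN).
#' * `tc_params(delta, l, Lc)` - thick chain: a discrete chain of segments of
#'   length `l` whose local radius of curvature is bounded below by the tube
#'   radius `delta`, capturing excluded-volume stiffening at low salt.
#'
#' All lengths in nm, moduli in pN.
#'
#' @param Lp,Lc,K,LK,delta,l Model parameters (see Details).
#' @return A classed list usable by [model_extension()] / [model_force()].
#' @name elastic_params
NULL

new_elastic_params <- function(tag, values) {
  bad <- !vapply(values, function(v) is.numeric(v) && length(v) == 1L &&
                   is.finite(v), logical(1))
  if (any(bad)) stop("elastic parameters must be finite scalars: ",
                     paste(names(values)[bad], collapse = ", "))
  structure(c(list(model = tag), values),
            class = c(paste0(tag, "_params"), "elastic_params"))
}

#' @rdname elastic_params
#' @export
wlc_params <- function(Lp, Lc) {
  if (Lp <= 0 || Lc <= 0) stop("wlc_params: Lp and Lc must be positive")
  new_elastic_params("wlc", list(Lp = Lp, Lc = Lc))
}

#' @rdname elastic_params
#' @export
ewlc_params <- function(Lp, Lc, K) {
  if (Lp <= 0 || Lc <= 0 || K <= 0)
    stop("ewlc_params: Lp, Lc and K must be positive")
  new_elastic_params("ewlc", list(Lp = Lp, Lc = Lc, K = K))
}

#' @rdname elastic_params
#' @export
exfjc_params <- function(LK, Lc, K) {
  if (LK <= 0 || Lc <= 0 || K <= 0)
    stop("exfjc_params: LK, Lc and K must be positive")
  new_elastic_params("exfjc", list(LK = LK, Lc = Lc, K = K))
}

#' @rdname elastic_params
#' @export
tc_params <- function(delta, l, Lc) {
  if (delta < 0 || l <= 0 || Lc <= 0)
    stop("tc_params: need delta >= 0, l > 0, Lc > 0")
  new_elastic_params("tc", list(delta = delta, l = l, Lc = Lc))
}

#' @export
print.elastic_params <- function(x, ...) {
  vals <- unlist(x[setdiff(names(x), "model")])
  cat(sprintf("<%s> %s\n", toupper(x$model),
              paste(sprintf("%s = %.4g", names(vals), vals), collapse = ", ")))
  invisible(x)
}

#' Marko-Siggia worm-like chain force
#'
#' Interpolation formula for the WLC restoring force at relative extension
#' `z = x / Lc`:
#' `f = (kBT / Lp) * (1 / (4 (1 - z)^2) - 1/4 + z)`.
#'
#' @param z Relative extension(s) in `[0, 1)`.
#' @param Lp Persistence length, nm.
#' @param cond [conditions()] object (supplies kBT); default 25 C.
#' @return Force(s) in pN.
#' @examples
#' wlc_force(0.5, Lp = 0.76) # ~6.77 pN
#' @export
wlc_force <- function(z, Lp, cond = NULL) {
  cond <- default_conditions(cond)
  if (Lp <= 0) stop("wlc_force: Lp must be positive")
  if (any(!is.finite(z)) || any(z < 0) || any(z >= 1))
    stop("wlc_force: relative extension must lie in [0, 1)")
  (cond$thermal_energy / Lp) * (1 / (4 * (1 - z)^2) - 0.25 + z)
}

# Inverse Marko-Siggia: relative extension at force f (vectorised).
# Bisection on z in [0, 1) followed by Newton polishing; the WLC force is
# strictly increasing in z so the bracket never fails.
wlc_inverse_z <- function(f, Lp, cond = NULL) {
  cond <- default_conditions(cond)
  if (Lp <= 0) stop("wlc_inverse_z: Lp must be positive")
  if (any(!is.finite(f)) || any(f < 0))
    stop("wlc_inverse_z: force must be finite and >= 0")
  ft <- f * Lp / cond$thermal_energy   # dimensionless f Lp / kBT
  g <- function(z) 1 / (4 * (1 - z)^2) - 0.25 + z
  lo <- rep(0, length(ft)); hi <- rep(1 - 1e-14, length(ft))
  for (i in 1:60) {
    mid <- 0.5 * (lo + hi)
    high <- g(mid) > ft
    hi[high] <- mid[high]; lo[!high] <- mid[!high]
  }
  z <- 0.5 * (lo + hi)
  for (i in 1:3) {                     # Newton polish
    dz <- (g(z) - ft) / (1 / (2 * (1 - z)^3) + 1)
    z <- pmin(pmax(z - dz, 0), 1 - 1e-14)
  }
  z[f == 0] <- 0
  z
}

#' Model extension at a given force
#'
#' Generic force -> extension relation for the elasticity models. Each
#' method returns the mean end-to-end extension (nm) of a chain with the
#' given parameters held at force `f` (pN). All relations are strictly
#' increasing in force and vanish at zero force.
#'
#' @param params An [elastic_params] object.
#' @param f Force(s), pN, `>= 0`.
#' @param cond [conditions()] object; default 25 C.
#' @param ... Passed to methods (`n_quad` for the thick chain).
#' @return Extension(s) in nm.
#' @examples
#' model_extension(exfjc_params(1.91, 7857, 760), 10) # ~6247 nm
#' @export
model_extension <- function(params, f, cond = NULL, ...) {
  UseMethod("model_extension")
}

#' @export
model_extension.wlc_params <- function(params, f, cond = NULL, ...) {
  params$Lc * wlc_inverse_z(f, params$Lp, cond)
}

#' @export
model_extension.ewlc_params <- function(params, f, cond = NULL, ...) {
  params$Lc * wlc_inverse_z(f, params$Lp, cond) * (1 + f / params$K)
}

#' @export
model_extension.exfjc_params <- function(params, f, cond = NULL, ...) {
  cond <- default_conditions(cond)
  if (any(!is.finite(f)) || any(f < 0))
    stop("model_extension: force must be finite and >= 0")
  b <- f * params$LK / cond$thermal_energy
  lang <- ifelse(b < 1e-4,
                 b / 3 - b^3 / 45,            # series, avoids 0/0
                 1 / tanh(b) - 1 / b)
  params$Lc * lang * (1 + f / params$K)
}

#' @export
model_extension.tc_params <- function(params, f, cond = NULL, n_quad = 48,
                                      Lp_local = 0, ...) {
  cond <- default_conditions(cond)
  if (any(!is.finite(f)) || any(f < 0))
    stop("model_extension: force must be finite and >= 0")
  params$Lc * tc_relative_extension(f, params$delta, params$l,
                                    kBT = cond$thermal_energy, n_quad = n_quad,
                                    Lp_local = Lp_local)
}

#' Model force at a given extension
#'
#' Numeric inverse of [model_extension()]: the force (pN) at which a chain
#' with the given parameters has mean extension `x` (nm). The WLC uses the
#' closed-form Marko-Siggia expression; the extensible models are inverted
#' by vectorised bisection (the relations are strictly monotone); the thick
#' chain is inverted per point with [stats::uniroot()].
#'
#' @inheritParams model_extension
#' @param x Extension(s), nm, `>= 0`.
#' @param f_max Upper bracket for the inversion, pN.
#' @return Force(s) in pN.
#' @export
model_force <- function(params, x, cond = NULL, ...) {
  UseMethod("model_force")
}

#' @export
model_force.wlc_params <- function(params, x, cond = NULL, ...) {
  if (any(x < 0) || any(x >= params$Lc))
    stop("model_force: extension must lie in [0, Lc)")
  wlc_force(x / params$Lc, params$Lp, cond)
}

# shared monotone bisection in force
.force_bisect <- function(params, x, cond, f_max) {
  if (any(!is.finite(x)) || any(x < 0))
    stop("model_force: extension must be finite and >= 0")
  lo <- rep(0, length(x)); hi <- rep(f_max, length(x))
  for (i in 1:80) {
    mid <- 0.5 * (lo + hi)
    high <- model_extension(params, mid, cond) > x
    hi[high] <- mid[high]; lo[!high] <- mid[!high]
  }
  out <- 0.5 * (lo + hi)
  out[x == 0] <- 0
  out
}

#' @rdname model_force
#' @export
model_force.ewlc_params <- function(params, x, cond = NULL, f_max = 1e4, ...) {
  .force_bisect(params, x, cond, f_max)
}

#' @rdname model_force
#' @export
model_force.exfjc_params <- function(params, x, cond = NULL, f_max = 1e4, ...) {
  .force_bisect(params, x, cond, f_max)
}

#' @rdname model_force
#' @export
model_force.tc_params <- function(params, x, cond = NULL, f_max = 200, ...) {
  if (any(!is.finite(x)) || any(x < 0) || any(x >= params$Lc))
    stop("model_force: extension must lie in [0, Lc)")
  vapply(x, function(xi) {
    if (xi == 0) return(0)
    stats::uniroot(function(ff) model_extension(params, ff, cond) - xi,
                   lower = 0, upper = f_max, tol = 1e-12)$root
  }, numeric(1))
}

#' Inextensible WLC extension at a given force
#'
#' Convenience wrapper around the numeric inversion of the Marko-Siggia
#' relation: solves `wlc_force(x / Lc, Lp) = f` for the extension `x`.
#'
#' @param f Force(s), pN, `>= 0`.
#' @param params A [wlc_params()] object.
#' @param cond [conditions()] object.
#' @return Extension(s), nm, in `[0, Lc)`.
#' @export
wlc_extension <- function(f, params, cond = NULL) {
  stopifnot(inherits(params, "wlc_params"))
  model_extension(params, f, cond)
}

#' @rdname wlc_extension
#' @param params_e An [ewlc_params()] object.
#' @export
ewlc_extension <- function(f, params_e, cond = NULL) {
  stopifnot(inherits(params_e, "ewlc_params"))
  model_extension(params_e, f, cond)
}

#' @rdname wlc_extension
#' @param params_j An [exfjc_params()] object.
#' @export
exfjc_extension <- function(f, params_j, cond = NULL) {
  stopifnot(inherits(params_j, "exfjc_params"))
  model_extension(params_j, f, cond)
}

#' @rdname wlc_extension
#' @param params_t A [tc_params()] object.
#' @param Lp_local Optional intrinsic bending persistence length (nm) added
#'   on top of the tube-curvature constraint; 0 (default) means all chain
#'   stiffness comes from the thickness.
#' @param n_quad Quadrature order for the thick-chain transfer operator.
#' @export
tc_extension <- function(f, params_t, Lp_local = 0, cond = NULL, n_quad = 48) {
  stopifnot(inherits(params_t, "tc_params"))
  model_extension(params_t, f, cond, n_quad = n_quad, Lp_local = Lp_local)
}
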