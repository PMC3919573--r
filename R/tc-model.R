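# Thick-chain (tube-constrained discrete chain) force-extension relation.
#
# The chain is a sequence of bonds of length l. Self-avoidance of a tube of
# radius delta bounds the local radius of curvature from below: three
# consecutive beads must lie on a circle of radius >= delta, which for bond
# length l restricts the turning angle gamma between successive bonds to
# sin(gamma/2) <= l / (2 delta). Under tension f each bond carries a weight
# exp(f l cos(theta) / kBT). The mean relative extension of the infinite
# chain is the expectation of cos(theta) under the dominant eigenfunction of
# the (azimuthally reduced, symmetrised) transfer operator.
#
# When delta <= l/2 the constraint is inactive and the model is exactly the
# discrete freely-jointed chain of segment l (Langevin function). The
# operator is discretised with Gauss-Legendre quadrature in cos(theta) and
# the dominant eigenvector found by power iteration.

# Fraction of the azimuth for which the turning-angle constraint holds,
# for all pairs of polar cosines u, u' (matrix). cos(gamma_max) = 1 - 2 s^2
# with s = min(1, l / (2 delta)).
.tc_phi_fraction <- function(u, cos_gamma_max) {
  su <- sqrt(pmax(0, 1 - u^2))
  num <- cos_gamma_max - outer(u, u)
  den <- outer(su, su)
  arg <- ifelse(den > 0, num / den, ifelse(num <= 0, -1, 1))
  acos(pmin(1, pmax(-1, arg))) / pi
}

# Azimuthal kernel integral with an optional intrinsic bending weight
# exp(beps * cos gamma), beps = Lp_local / l (dimensionless bending
# stiffness). Reduces to the allowed-azimuth fraction when beps = 0.
.tc_phi_kernel <- function(u, cos_gamma_max, beps, n_phi = 24) {
  frac <- .tc_phi_fraction(u, cos_gamma_max)
  if (beps == 0) return(frac)
  su <- sqrt(pmax(0, 1 - u^2))
  gq <- pracma::gaussLegendre(n_phi, 0, 1)   # scaled to [0, phi_max] per pair
  out <- matrix(0, length(u), length(u))
  ss <- outer(su, su); uu <- outer(u, u); phimax <- frac * pi
  for (k in seq_len(n_phi)) {
    out <- out + gq$w[k] * exp(beps * (uu + ss * cos(gq$x[k] * phimax)))
  }
  out * frac                                  # (phi_max/pi) * mean weight
}

# Mean relative extension <cos theta> at force(s) f (pN). Vectorised over f
# with warm-started power iteration; returns values in [0, 1). Lp_local > 0
# adds an intrinsic bending stiffness on top of the tube constraint.
tc_relative_extension <- function(f, delta, l, kBT = 4.114, n_quad = 48,
                                  Lp_local = 0) {
  if (delta < 0 || l <= 0) stop("thick chain: need delta >= 0 and l > 0")
  s <- min(1, l / (2 * delta))
  if (s >= 1 && Lp_local == 0) {        # constraint inactive: discrete FJC
    b <- f * l / kBT
    return(ifelse(b < 1e-4, b / 3 - b^3 / 45, 1 / tanh(b) - 1 / b))
  }
  gl <- pracma::gaussLegendre(n_quad, -1, 1)
  u <- gl$x; w <- gl$w
  phi <- .tc_phi_kernel(u, 1 - 2 * s^2, Lp_local / l)
  sw <- sqrt(w)
  base <- outer(sw, sw) * phi           # force-independent part of the kernel
  out <- numeric(length(f))
  v <- rep(1 / sqrt(n_quad), n_quad)
  ord <- order(f)                       # ascending force => good warm starts
  for (idx in ord) {
    fi <- f[idx]
    if (fi == 0) { out[idx] <- 0; next }
    a <- fi * l / kBT
    B <- base * exp(outer(u, u, function(p, q) 0.5 * a * (p + q)))
    for (it in 1:1000) {
      v2 <- B %*% v
      v2 <- v2 / sqrt(sum(v2^2))
      if (max(abs(v2 - v)) < 1e-13) { v <- as.numeric(v2); break }
      v <- as.numeric(v2)
    }
    out[idx] <- sum(v^2 * u)
  }
  out
}
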