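#' Pulling-curve container
#'
#' A pulling curve is an ordered series of (position, force[, time]) samples
#' from a constant-velocity optical-tweezers experiment. `kind = "FDC"`
#' means the position is the raw trap-pipette distance (it still contains
#' the bead displacement in the trap); `kind = "FEC"` means the position is
#' the molecular end-to-end extension. Units: nm, pN, s.
#'
#' @param position Positions, nm (distance for FDC, extension for FEC).
#' @param force Forces, pN.
#' @param time Optional sample times, s (must be nondecreasing).
#' @param kind `"FEC"` or `"FDC"`.
#' @param sample_rate Acquisition rate, Hz.
#' @return A data frame of class `pulling_curve` with attributes `kind` and
#'   `sample_rate`.
#' @export
pulling_curve <- function(position, force, time = NULL,
                          kind = c("FEC", "FDC"), sample_rate = 200) {
  kind <- match.arg(kind)
  if (length(position) != length(force))
    stop("pulling_curve: position and force lengths differ")
  if (any(!is.finite(position)) || any(!is.finite(force)))
    stop("pulling_curve: positions and forces must be finite")
  if (!is.null(time)) {
    if (length(time) != length(force) || any(!is.finite(time)))
      stop("pulling_curve: time must be finite and match the sample count")
    if (is.unsorted(time)) stop("pulling_curve: time must be nondecreasing")
  }
  df <- data.frame(position = as.numeric(position), force = as.numeric(force))
  if (!is.null(time)) df$time <- as.numeric(time)
  structure(df, kind = kind, sample_rate = sample_rate,
            class = c("pulling_curve", "data.frame"))
}

#' @rdname pulling_curve
#' @param x A `pulling_curve`.
#' @export
curve_kind <- function(x) attr(x, "kind")

#' @rdname pulling_curve
#' @export
sample_rate <- function(x) attr(x, "sample_rate")

#' @export
print.pulling_curve <- function(x, ...) {
  cat(sprintf("<pulling_curve %s> %d samples @ %s Hz, force %.3g-%.3g pN, position %.4g-%.4g nm\n",
              curve_kind(x), nrow(x),
              format(sample_rate(x)), min(x$force), max(x$force),
              min(x$position), max(x$position)))
  invisible(x)
}

# rebuild preserving metadata
.recurve <- function(template, position, force, time = NULL,
                     kind = curve_kind(template),
                     rate = sample_rate(template)) {
  pulling_curve(position, force, time, kind = kind, sample_rate = rate)
}

#' Harmonic trap model
#'
#' @param stiffness Trap stiffness k, pN/nm (typical value 0.07).
#' @return A list of class `trap_model`.
#' @export
trap_model <- function(stiffness = 0.07) {
  if (!is.numeric(stiffness) || length(stiffness) != 1L || stiffness <= 0)
    stop("trap_model: stiffness must be a positive scalar", call. = FALSE)
  structure(list(stiffness = stiffness), class = "trap_model")
}

#' Convert between force-distance and force-extension curves
#'
#' In the harmonic-trap approximation the molecular extension is the
#' measured trap-pipette distance minus the bead displacement in the trap:
#' `x = x_d - f / k`. `fdc_to_fec()` applies this correction;
#' `fec_to_fdc()` is its exact inverse (`x_d = x + f / k`), used when
#' synthesising raw-looking traces.
#'
#' @param curve A [pulling_curve()] of the appropriate kind.
#' @param trap A [trap_model()].
#' @return A [pulling_curve()] of the converted kind; forces are unchanged.
#' @examples
#' fdc <- pulling_curve(1000, 14, kind = "FDC")
#' fdc_to_fec(fdc, trap_model(0.07))$position # 800
#' @export
fdc_to_fec <- function(curve, trap = trap_model()) {
  stopifnot(inherits(curve, "pulling_curve"), inherits(trap, "trap_model"))
  if (curve_kind(curve) != "FDC") stop("fdc_to_fec: input must be an FDC")
  .recurve(curve, curve$position - curve$force / trap$stiffness,
           curve$force, curve$time, kind = "FEC")
}

#' @rdname fdc_to_fec
#' @export
fec_to_fdc <- function(curve, trap = trap_model()) {
  stopifnot(inherits(curve, "pulling_curve"), inherits(trap, "trap_model"))
  if (curve_kind(curve) != "FEC") stop("fec_to_fdc: input must be an FEC")
  .recurve(curve, curve$position + curve$force / trap$stiffness,
           curve$force, curve$time, kind = "FDC")
}

#' Reduce a curve to a target bandwidth
#'
#' Non-overlapping boxcar averaging: blocks of `sample_rate / bandwidth`
#' consecutive samples are replaced by their means, so a 200 Hz trace
#' filtered to 2 Hz keeps one point per 100 raw samples and white force
#' noise shrinks by the square root of the block size. A trailing partial
#' block is dropped.
#'
#' @param curve A [pulling_curve()].
#' @param bandwidth Target bandwidth, Hz; must satisfy
#'   `sample_rate >= 2 * bandwidth`.
#' @return The filtered [pulling_curve()] with updated sample rate.
#' @export
bandwidth_filter <- function(curve, bandwidth = 2) {
  stopifnot(inherits(curve, "pulling_curve"))
  rate <- sample_rate(curve)
  if (!is.finite(rate) || rate < 2 * bandwidth)
    stop("bandwidth_filter: sample rate must be at least twice the target bandwidth")
  block <- max(1L, as.integer(round(rate / bandwidth)))
  n <- (nrow(curve) %/% block) * block
  if (n < block) stop("bandwidth_filter: curve shorter than one averaging block")
  grp <- rep(seq_len(n %/% block), each = block)
  avg <- function(v) as.numeric(tapply(v[seq_len(n)], grp, mean))
  .recurve(curve, avg(curve$position), avg(curve$force),
           if (!is.null(curve$time)) avg(curve$time),
           rate = rate / block)
}

#' Restrict a curve to a force window
#'
#' Keeps the samples with `fmin <= f <= fmax` (both inclusive), preserving
#' order. Elasticity fits use 10-40 pN by default: below ~10 pN secondary
#' structure contaminates the elastic response.
#'
#' @param curve A [pulling_curve()].
#' @param window A [fit_window()] (or list with `fmin`, `fmax`).
#' @return The windowed [pulling_curve()].
#' @export
window_by_force <- function(curve, window = fit_window()) {
  stopifnot(inherits(curve, "pulling_curve"))
  keep <- curve$force >= window$fmin & curve$force <= window$fmax
  if (!any(keep))
    stop("window_by_force: no data in window [", window$fmin, ", ",
         window$fmax, "] pN")
  .recurve(curve, curve$position[keep], curve$force[keep], curve$time[keep])
}

#' Force window for fitting
#'
#' @param fmin,fmax Window bounds in pN, `0 <= fmin < fmax`.
#' @return A list of class `fit_window`.
#' @export
fit_window <- function(fmin = 10, fmax = 40) {
  if (!(fmin >= 0 && fmin < fmax)) stop("fit_window: need 0 <= fmin < fmax")
  structure(list(fmin = fmin, fmax = fmax), class = "fit_window")
}
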