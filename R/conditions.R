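#' Experimental ionic and thermal conditions
#'
#' Bundles the quantities every elasticity calculation needs: temperature,
#' thermal energy, salt species and concentration. Units are fixed
#' package-wide: force in pN, length in nm, energy in pN nm, concentration
#' in mM. The thermal energy defaults to 4.114 pN nm at 298.15 K (25 C,
#' the temperature at which the pulling experiments are performed) and is
#' scaled linearly for other temperatures.
#'
#' Monovalent buffers contribute a fixed background of cations (9 mM by
#' default, from Tris/EDTA); this offset is added to the nominal NaCl
#' concentration wherever an effective cation concentration is needed.
#' For divalent salt the competing monovalent background is negligible in
#' the concentration range of interest and the nominal value is used as is.
#'
#' @param salt_type `"monovalent"` (e.g. NaCl) or `"divalent"` (e.g. MgCl2).
#' @param concentration_mM Nominal added salt concentration in mM.
#' @param temperature_K Absolute temperature in kelvin.
#' @param buffer_offset_mM Monovalent cation background from the buffer, mM.
#' @return An object of class `fec_conditions`.
#' @examples
#' cond <- conditions("monovalent", 1000)
#' cond$thermal_energy # ~4.114 pN nm
#' @export
conditions <- function(salt_type = c("monovalent", "divalent"),
                       concentration_mM = 1000,
                       temperature_K = 298.15,
                       buffer_offset_mM = 9) {
  salt_type <- match.arg(salt_type)
  stopifnot(is.numeric(concentration_mM), length(concentration_mM) == 1L,
            concentration_mM >= 0, is.finite(concentration_mM),
            temperature_K > 0, buffer_offset_mM >= 0)
  kBT <- 4.114 * temperature_K / 298.15
  structure(
    list(temperature = temperature_K,
         thermal_energy = kBT,
         salt_type = salt_type,
         concentration = concentration_mM,
         buffer_monovalent_offset = buffer_offset_mM),
    class = "fec_conditions")
}

#' @export
print.fec_conditions <- function(x, ...) {
  cat(sprintf("Conditions: %s salt %.3g mM (+%g mM buffer), T = %.2f K, kBT = %.4f pN nm\n",
              x$salt_type, x$concentration, x$buffer_monovalent_offset,
              x$temperature, x$thermal_energy))
  invisible(x)
}

default_conditions <- function(cond = NULL) {
  if (is.null(cond)) conditions() else {
    stopifnot(inherits(cond, "fec_conditions"))
    cond
  }
}

#' Effective cation concentration
#'
#' For monovalent salt the buffer contributes a fixed monovalent background
#' that adds to the nominal concentration; for divalent salt the monovalent
#' competition is negligible and the nominal concentration is returned.
#'
#' @param nominal_mM Nominal salt concentration(s), mM.
#' @param salt_type `"monovalent"` or `"divalent"`.
#' @param buffer_offset_mM Monovalent background, mM (default 9).
#' @return Effective cation concentration(s), mM.
#' @examples
#' effective_cation_concentration(10, "monovalent") # 19
#' effective_cation_concentration(10, "divalent")   # 10
#' @export
effective_cation_concentration <- function(nominal_mM,
                                           salt_type = c("monovalent", "divalent"),
                                           buffer_offset_mM = 9) {
  salt_type <- match.arg(salt_type)
  stopifnot(all(nominal_mM >= 0))
  if (salt_type == "monovalent") nominal_mM + buffer_offset_mM else nominal_mM
}

#' Debye screening length
#'
#' Computes the Debye length lambda = sqrt(eps_r eps0 kB T / (2 NA e^2 I))
#' for the ionic strength implied by the conditions: I = c_eff for a 1:1
#' salt and I = 3 c + offset for a 2:1 salt (MgCl2), in mM. Uses the
#' relative permittivity of water at 25 C (78.3).
#'
#' @param cond A [conditions()] object.
#' @return Debye length in nm.
#' @examples
#' # ~0.30 nm at 1 M monovalent salt
#' debye_length(conditions("monovalent", 1000, buffer_offset_mM = 0))
#' @export
debye_length <- function(cond) {
  cond <- default_conditions(cond)
  ionic <- if (cond$salt_type == "monovalent") {
    cond$concentration + cond$buffer_monovalent_offset
  } else {
    3 * cond$concentration + cond$buffer_monovalent_offset
  }
  if (ionic <= 0) stop("debye_length: total ionic strength must be positive")
  e  <- 1.602176634e-19   # C
  e0 <- 8.8541878128e-12  # F/m
  kB <- 1.380649e-23      # J/K
  NA_ <- 6.02214076e23
  er <- 78.3
  I_m3 <- ionic                       # mM == mol/m^3
  lam_m <- sqrt(er * e0 * kB * cond$temperature / (2 * NA_ * e^2 * I_m3))
  lam_m * 1e9
}
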