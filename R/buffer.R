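#' Phosphate-buffered saline release-medium description
#'
#' Describes the PBS release/swelling medium: total phosphate, NaCl, pH,
#' temperature, a reference density measured at a reference temperature,
#' and the HPO4^2-/H2PO4^- speciation ratio at the working pH (about 1.6
#' at pH 7.40).
#'
#' @param phosphate_total total phosphate, mol/L (default 0.010).
#' @param nacl NaCl concentration, mol/L (default 0.154).
#' @param pH working pH (default 7.40).
#' @param temperature_C working temperature, degC (default 37).
#' @param density_ref measured solution density, g/cm^3 (default 1.098).
#' @param density_ref_temperature_C temperature of that measurement, degC
#'   (default 20).
#' @param hpo4_to_h2po4_ratio `[HPO4^2-]/[H2PO4^-]` at the working pH
#'   (default 1.6).
#' @return An object of class `buffer_spec`.
#' @export
#' @examples
#' b <- buffer_spec()
#' ionic_strength(b)      # phosphate 0.026, total 0.180, c_e 0.090 M
#' buffer_density_at(b, 37)  # ~1.093 g/cm^3
buffer_spec <- function(phosphate_total = 0.010, nacl = 0.154, pH = 7.40,
                        temperature_C = 37, density_ref = 1.098,
                        density_ref_temperature_C = 20,
                        hpo4_to_h2po4_ratio = 1.6) {
  if (phosphate_total < 0 || nacl < 0)
    stop("concentrations must be >= 0", call. = FALSE)
  if (hpo4_to_h2po4_ratio < 0)
    stop("'hpo4_to_h2po4_ratio' must be >= 0", call. = FALSE)
  structure(list(phosphate_total = phosphate_total, nacl = nacl, pH = pH,
                 temperature_C = temperature_C, density_ref = density_ref,
                 density_ref_temperature_C = density_ref_temperature_C,
                 hpo4_to_h2po4_ratio = hpo4_to_h2po4_ratio),
            class = "buffer_spec")
}

#' Density of pure water
#'
#' Kell (1975) polynomial for the density of air-free water at atmospheric
#' pressure, valid between 0 and 100 degC.
#'
#' @param temperature_C temperature in degC, in (0, 100).
#' @return Density in g/cm^3.
#' @export
water_density <- function(temperature_C) {
  if (any(temperature_C <= 0) || any(temperature_C >= 100))
    stop("water density formula valid only for (0, 100) degC", call. = FALSE)
  t <- temperature_C
  num <- 999.83952 + 16.945176 * t - 7.9870401e-3 * t^2 -
    46.170461e-6 * t^3 + 105.56302e-9 * t^4 - 280.54253e-12 * t^5
  num / (1 + 16.879850e-3 * t) / 1000
}

#' Scale a buffer density to another temperature
#'
#' Rescales the measured reference density by the ratio of pure-water
#' densities at the target and reference temperatures, assuming the
#' solution tracks the thermal expansion of water.
#'
#' @param spec a [buffer_spec()].
#' @param target_temperature_C temperature to scale to, degC.
#' @return Density in g/cm^3 at the target temperature.
#' @export
buffer_density_at <- function(spec, target_temperature_C = spec$temperature_C) {
  stopifnot(inherits(spec, "buffer_spec"))
  spec$density_ref * water_density(target_temperature_C) /
    water_density(spec$density_ref_temperature_C)
}

#' Ionic strength and mobile-ion concentration of the buffer
#'
#' Computes `I = 1/2 * sum(c_i z_i^2)` for the phosphate subsystem plus
#' fully dissociated NaCl. Phosphate is split between H2PO4^- and HPO4^2-
#' by `hpo4_to_h2po4_ratio`; the sodium-counting convention takes sodium
#' equivalent to twice the total phosphate (dibasic salt basis) with a
#' chloride makeweight restoring electroneutrality. The Donnan treatment
#' replaces the medium by an NaCl solution of equal ionic strength, so the
#' equivalent mobile-ion parameter is `c_e = I_total / 2` (mol/L).
#'
#' @param spec a [buffer_spec()].
#' @param sodium_per_phosphate sodium ions counted per phosphate (default
#'   2; the shipped, documented convention).
#' @return A list with `phosphate` (phosphate-subsystem ionic strength),
#'   `total` (mol/L), and `c_e` (mol/L).
#' @export
ionic_strength <- function(spec, sodium_per_phosphate = 2) {
  stopifnot(inherits(spec, "buffer_spec"))
  r <- spec$hpo4_to_h2po4_ratio
  h2po4 <- spec$phosphate_total / (1 + r)
  hpo4 <- spec$phosphate_total * r / (1 + r)
  na <- sodium_per_phosphate * spec$phosphate_total
  anion_charge <- h2po4 + 2 * hpo4
  cl <- max(na - anion_charge, 0)      # electroneutrality makeweight
  I_phos <- 0.5 * (h2po4 * 1 + hpo4 * 4 + na * 1 + cl * 1)
  I_total <- I_phos + spec$nacl        # 1:1 electrolyte: I = c
  list(phosphate = I_phos, total = I_total, c_e = I_total / 2)
}
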