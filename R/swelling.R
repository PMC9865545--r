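#' Dry-matrix composition and densities
#'
#' Composition of one freeze-dried matrix: TA and CHDG loads expressed as
#' percentages of the collagen mass, the pycnometric density of the dry
#' matrix, and the collagen density.
#'
#' @param rho_matrix dry matrix density, g/cm^3.
#' @param ta_pct,chdg_pct loads as % of collagen mass (default 0).
#' @param rho_coll collagen density, g/cm^3 (default 1.195).
#' @return An object of class `matrix_composition`.
#' @export
matrix_composition <- function(rho_matrix, ta_pct = 0, chdg_pct = 0,
                               rho_coll = 1.195) {
  if (ta_pct < 0 || chdg_pct < 0) stop("loads must be >= 0", call. = FALSE)
  if (rho_matrix <= 0 || rho_coll <= 0)
    stop("densities must be positive", call. = FALSE)
  structure(list(ta_pct = ta_pct, chdg_pct = chdg_pct,
                 rho_matrix = rho_matrix, rho_coll = rho_coll),
            class = "matrix_composition")
}

#' Remove the capillary contribution from gravimetric uptake
#'
#' Subtracts the buffer mechanically held in the macro-pores (measured by
#' ethanol pycnometry as a pore volume per gram of dry matrix) from a raw
#' uptake series, flooring the result at 1 g/g: a swollen sample cannot
#' weigh less than its dry mass.
#'
#' @param raw_uptake numeric vector, raw swollen/dry mass ratios (g/g).
#' @param pore_volume_per_gram pore volume, cm^3 per g of dry matrix
#'   (>= 0).
#' @param rho_buffer buffer density at the working temperature, g/cm^3.
#' @return Corrected uptake vector (g/g).
#' @export
capillary_correct <- function(raw_uptake, pore_volume_per_gram, rho_buffer) {
  if (pore_volume_per_gram < 0)
    stop("'pore_volume_per_gram' must be >= 0", call. = FALSE)
  pmax(raw_uptake - pore_volume_per_gram * rho_buffer, 1)
}

#' Equilibrium volume swelling ratios and polymer volume fraction
#'
#' Converts an equilibrium mass uptake `q_w` (swollen mass / dry mass,
#' g/g) into volume swelling ratios and the collagen volume fraction
#' `nu2eq`, under one of two limiting cases:
#'
#' * `"released"`: the loaded antimicrobials have left the matrix, so the
#'   dry solid is collagen alone:
#'   `q_v_coll = 1 + (q_w - 1) * rho_coll / rho_buffer`, `nu2eq = 1/q_v_coll`.
#' * `"loaded"`: nothing has been released;
#'   `q_v_matrix = 1 + (q_w - 1) * rho_matrix / rho_buffer`, and
#'   `q_v_coll` is the total swollen volume divided by the collagen dry
#'   volume obtained from the composition mass fractions (a volume-additive
#'   convention; reproduces pycnometric table values to about 2%).
#'
#' @param q_w equilibrium uptake, g/g (> 1).
#' @param comp a [matrix_composition()].
#' @param rho_buffer buffer density, g/cm^3 (default 1.093, PBS at 37 degC).
#' @param release_case `"released"` or `"loaded"`.
#' @return An object of class `equilibrium_swelling` with fields `q_w`,
#'   `release_case`, `q_v_matrix`, `q_v_coll`, `nu2eq`.
#' @export
#' @examples
#' comp <- matrix_composition(rho_matrix = 1.195)
#' equilibrium_volume_fractions(6.80, comp)  # q_v_coll 7.34, nu2eq 0.136
equilibrium_volume_fractions <- function(q_w, comp, rho_buffer = 1.093,
                                         release_case = c("released",
                                                          "loaded")) {
  stopifnot(inherits(comp, "matrix_composition"))
  release_case <- match.arg(release_case)
  if (q_w <= 1) stop("'q_w' must exceed 1 g/g", call. = FALSE)
  if (release_case == "released") {
    q_v_coll <- 1 + (q_w - 1) * comp$rho_coll / rho_buffer
    q_v_matrix <- q_v_coll   # dry solid is collagen alone in this limit
  } else {
    q_v_matrix <- 1 + (q_w - 1) * comp$rho_matrix / rho_buffer
    w_coll <- 1 / (1 + comp$ta_pct / 100 + comp$chdg_pct / 100)
    v_coll_dry <- w_coll / comp$rho_coll            # cm^3 per g dry matrix
    v_swollen <- 1 / comp$rho_matrix + (q_w - 1) / rho_buffer
    q_v_coll <- v_swollen / v_coll_dry
  }
  structure(list(q_w = q_w, release_case = release_case,
                 q_v_matrix = q_v_matrix, q_v_coll = q_v_coll,
                 nu2eq = 1 / q_v_coll),
            class = "equilibrium_swelling")
}

#' Donnan excess mobile-ion concentration
#'
#' Difference in total mobile-ion concentration between the interior of a
#' charged gel and the external bath at Donnan equilibrium with a 1:1
#' electrolyte: `delta_c = sqrt(c_p^2 + 4*c_e^2) - 2*c_e`, assuming equal
#' mean ionic activity coefficients inside and outside.
#'
#' @param c_p fixed-charge concentration inside the gel, mol/cm^3 (>= 0).
#' @param c_e mobile-ion parameter of the bath (half the total mobile-ion
#'   concentration), mol/cm^3 (> 0). Note the interface unit conversion:
#'   0.090 mol/L = 9.0e-5 mol/cm^3.
#' @return `delta_c` in mol/cm^3 (>= 0).
#' @export
#' @examples
#' donnan_delta_c(953e-8, 9.0e-5) * 1e7  # ~2.5
donnan_delta_c <- function(c_p, c_e) {
  if (any(c_p < 0)) stop("'c_p' must be >= 0", call. = FALSE)
  if (any(c_e <= 0)) stop("'c_e' must be > 0", call. = FALSE)
  sqrt(c_p^2 + 4 * c_e^2) - 2 * c_e
}

#' Flory-Huggins swelling parameters
#'
#' @param chi1 polymer-solvent interaction parameter (default 0.49,
#'   collagen-water).
#' @param v1 molar volume of the solvent, cm^3/mol (default 18.07, water
#'   near 37 degC).
#' @param nu20 polymer volume fraction at network formation (default 0.20,
#'   the collagen volume fraction of fresh hide).
#' @return An object of class `crosslink_params`.
#' @export
crosslink_params <- function(chi1 = 0.49, v1 = 18.07, nu20 = 0.20) {
  if (v1 <= 0) stop("'v1' must be positive", call. = FALSE)
  if (nu20 <= 0 || nu20 > 1) stop("'nu20' must be in (0, 1]", call. = FALSE)
  structure(list(chi1 = chi1, v1 = v1, nu20 = nu20),
            class = "crosslink_params")
}

#' Crosslink density from equilibrium swelling
#'
#' Degree of crosslinking (moles of effective network junctions per cm^3)
#' of a polyelectrolyte gel at equilibrium swelling. Both relations share
#' the numerator `V1*delta_c - [ln(1-nu) + nu + chi1*nu^2]`; the
#' denominator is `V1*(nu^(1/3) - nu/2)` for the Flory relation
#' (network formed in bulk) and
#' `V1*nu20*((nu/nu20)^(1/3) - nu/(2*nu20))` for the
#' Bray-Merrill/Ofner-Bubnis relation (network formed in solution at
#' polymer volume fraction `nu20`). With `nu20 = 1` the two coincide.
#'
#' @param nu2eq polymer volume fraction at equilibrium swelling, in (0, 1).
#' @param delta_c Donnan mobile-ion excess, mol/cm^3 (see
#'   [donnan_delta_c()]).
#' @param params a [crosslink_params()].
#' @param method `"bray_merrill"` (default) or `"flory"`.
#' @return An object of class `crosslink_result` with fields `dc`
#'   (mol/cm^3), `delta_c`, `nu2eq`, `method`.
#' @export
#' @examples
#' crosslink_density(0.136, 2.53e-7)$dc * 1e5  # ~58
crosslink_density <- function(nu2eq, delta_c, params = crosslink_params(),
                              method = c("bray_merrill", "flory")) {
  method <- match.arg(method)
  stopifnot(inherits(params, "crosslink_params"))
  if (nu2eq <= 0 || nu2eq >= 1) stop("'nu2eq' must be in (0, 1)",
                                     call. = FALSE)
  if (delta_c < 0) stop("'delta_c' must be >= 0", call. = FALSE)
  numerator <- params$v1 * delta_c -
    (log(1 - nu2eq) + nu2eq + params$chi1 * nu2eq^2)
  denominator <- if (method == "flory") {
    params$v1 * (nu2eq^(1 / 3) - nu2eq / 2)
  } else {
    params$v1 * params$nu20 *
      ((nu2eq / params$nu20)^(1 / 3) - nu2eq / (2 * params$nu20))
  }
  if (denominator <= 0)
    stop("swelling denominator non-positive: nu2eq = ", nu2eq,
         " too large relative to nu20 = ", params$nu20, call. = FALSE)
  structure(list(dc = numerator / denominator, delta_c = delta_c,
                 nu2eq = nu2eq, method = method),
            class = "crosslink_result")
}
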