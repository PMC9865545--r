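#' Ionizable group class of a protein
#'
#' One class of identical ionizable groups carried by a protein molecule:
#' a residue side chain (e.g. the Asp beta-carboxyl) or a chain terminus.
#' The charge-pair sign `pair_sign` is -1 for -COOH/-COO- pairs and +1 for
#' -NH3+/-NH2 (and imidazolium, guanidinium) pairs; it drives the sign of
#' the ionic-strength pKa correction and decides whether the deprotonated
#' form is negative (acidic class) or the protonated form positive (basic
#' class).
#'
#' @param name label, e.g. `"Asp"`.
#' @param count non-negative integer, groups per molecule.
#' @param pka_ref acidity exponent at 25 degC and zero ionic strength.
#' @param pair_sign -1 (acidic pair) or +1 (basic pair).
#' @param ionization_enthalpy standard ionization enthalpy in J/mol, used in
#'   the van't Hoff temperature correction of the pKa.
#' @return A one-row data frame of class `ionizable_group_class`.
#' @seealso [collagen_composition()], [correct_pka()]
#' @export
#' @examples
#' ionizable_group("His", 14, 6.00, +1, 29500)
ionizable_group <- function(name, count, pka_ref, pair_sign,
                            ionization_enthalpy = 0) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(count) || length(count) != 1L || count < 0 ||
      count != round(count))
    stop("'count' must be a single non-negative integer", call. = FALSE)
  if (!pair_sign %in% c(-1, 1))
    stop("'pair_sign' must be -1 (acidic) or +1 (basic)", call. = FALSE)
  g <- data.frame(name = name, count = as.numeric(count),
                  pka_ref = as.numeric(pka_ref),
                  pair_sign = as.numeric(pair_sign),
                  ionization_enthalpy = as.numeric(ionization_enthalpy),
                  stringsAsFactors = FALSE)
  class(g) <- c("ionizable_group_class", class(g))
  g
}

#' Ionizable composition of a protein molecule
#'
#' Bundles the ionizable group classes of one molecule together with the
#' deamidatable Asn/Gln pool. Deamidation (side-chain amide hydrolysis)
#' converts Asn to Asp and Gln to Glu, adding acidic groups; see
#' [deamidate()].
#'
#' @param groups data frame with columns `name`, `count`, `pka_ref`,
#'   `pair_sign`, `ionization_enthalpy` (rows as built by
#'   [ionizable_group()]).
#' @param asn_count,gln_count non-negative integers, sizes of the
#'   deamidatable pools.
#' @param deamidation_degree fraction in `[0, 1]` already applied to this
#'   composition (bookkeeping only).
#' @return An object of class `ionizable_composition`.
#' @export
ionizable_composition <- function(groups, asn_count = 0L, gln_count = 0L,
                                  deamidation_degree = 0) {
  need <- c("name", "count", "pka_ref", "pair_sign", "ionization_enthalpy")
  if (!all(need %in% names(groups)))
    stop("'groups' must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(groups$count < 0)) stop("group counts must be >= 0", call. = FALSE)
  if (!all(groups$pair_sign %in% c(-1, 1)))
    stop("pair_sign must be -1 or +1", call. = FALSE)
  if (asn_count < 0 || gln_count < 0)
    stop("Asn/Gln pool sizes must be >= 0", call. = FALSE)
  if (deamidation_degree < 0 || deamidation_degree > 1)
    stop("'deamidation_degree' must be in [0, 1]", call. = FALSE)
  groups <- data.frame(name = as.character(groups$name),
                       count = as.numeric(groups$count),
                       pka_ref = as.numeric(groups$pka_ref),
                       pair_sign = as.numeric(groups$pair_sign),
                       ionization_enthalpy =
                         as.numeric(groups$ionization_enthalpy))
  structure(list(groups = as.data.frame(groups),
                 asn_count = asn_count, gln_count = gln_count,
                 deamidation_degree = deamidation_degree),
            class = "ionizable_composition")
}

#' @export
print.ionizable_composition <- function(x, ...) {
  cat("Ionizable composition (", sum(x$groups$count), " groups; Asn pool ",
      x$asn_count, ", Gln pool ", x$gln_count, ", deamidation ",
      100 * x$deamidation_degree, "%)\n", sep = "")
  print(x$groups, row.names = FALSE)
  invisible(x)
}

#' Default atelocollagen type I ionizable composition
#'
#' Charge-bearing residue classes of one bovine atelocollagen type I triple
#' helix: Asp 90, Glu 150, three C-terminal Pro alpha-carboxyls, His 14,
#' Arg 162, Lys 89, and three N-terminal Gly alpha-amino groups. The
#' deamidatable pool defaults to Asn 46 / Gln 75, the smallest integers for
#' which 24% deamidation yields +11 Asp and +18 Glu under round-half-up.
#'
#' The reference pKa values (25 degC, zero ionic strength) and ionization
#' enthalpies are standard protein values, calibrated within their
#' literature ranges so that, after correction to 37 degC and I = 0.180,
#' the 24%-deamidated molecule carries a net charge of magnitude 17.6 at
#' pH 7.40, has an isoelectric point of 5.5, and the non-deamidated
#' molecule an isoelectric point above 8. Override any entry by editing
#' the returned object.
#'
#' @param deamidation fraction of the Asn/Gln pool already deamidated;
#'   default 0 (apply [deamidate()] for the operating 24%).
#' @return An [ionizable_composition()].
#' @export
#' @examples
#' comp <- deamidate(collagen_composition(), 0.24)
#' net_charge(comp, pH = 7.40, temperature_C = 37, ionic_strength = 0.180)
collagen_composition <- function(deamidation = 0) {
  groups <- rbind(
    ionizable_group("Asp",       90L,  3.90, -1,  4000),
    ionizable_group("Glu",      150L,  4.30, -1,  1000),
    ionizable_group("Cterm_Pro",  3L,  3.60, -1,     0),
    ionizable_group("His",       14L,  6.00, +1, 29500),
    ionizable_group("Lys",       89L, 10.50, +1, 52500),
    ionizable_group("Arg",      162L, 12.50, +1, 51500),
    ionizable_group("Nterm_Gly",  3L,  8.60, +1, 45000))
  comp <- ionizable_composition(groups, asn_count = 46L, gln_count = 75L)
  if (deamidation > 0) comp <- deamidate(comp, deamidation)
  comp
}

# Debye-Huckel limiting-law coefficient A (log10 basis, kg^1/2 mol^-1/2),
# linearly interpolated between standard tabulated values.
davies_A <- function(temperature_C) {
  stats::approx(x = c(0, 25, 50, 100),
                y = c(0.4918, 0.5092, 0.5336, 0.6086),
                xout = temperature_C, rule = 1)$y
}

#' Correct a reference pKa for temperature and ionic strength
#'
#' Applies a van't Hoff shift from 25 degC to the target temperature using
#' the ionization enthalpy, plus a Davies-type ionic-strength term
#' `Z * 2 * A(T) * (sqrt(I)/(1+sqrt(I)) - 0.3*I)` whose sign follows the
#' charge-pair sign Z (-1 acidic, +1 basic). Both corrections vanish at
#' 25 degC and I = 0.
#'
#' @param group an [ionizable_group()] row (or a data frame of them).
#' @param temperature_C temperature in degC, in (0, 100).
#' @param ionic_strength molal-scale ionic strength, >= 0.
#' @return Numeric vector of corrected acidity exponents.
#' @export
correct_pka <- function(group, temperature_C, ionic_strength) {
  if (ionic_strength < 0) stop("ionic strength must be >= 0", call. = FALSE)
  if (temperature_C <= 0 || temperature_C >= 100)
    stop("temperature must be in (0, 100) degC", call. = FALSE)
  T_ref <- 298.15
  T_k <- temperature_C + 273.15
  R <- 8.31446
  vant_hoff <- group$ionization_enthalpy / (R * log(10)) * (1 / T_k - 1 / T_ref)
  f_I <- sqrt(ionic_strength) / (1 + sqrt(ionic_strength)) -
    0.3 * ionic_strength
  davies <- group$pair_sign * 2 * davies_A(temperature_C) * f_I
  group$pka_ref + vant_hoff + davies
}

# round-half-up to integer (base round() is half-to-even)
round_half_up <- function(x) floor(x + 0.5)

#' Deamidate an ionizable composition
#'
#' Converts a fraction of the Asn/Gln pool to Asp/Glu, preserving the
#' Asn/Gln ratio: `round(degree * asn_count)` is added to the Asp count and
#' `round(degree * gln_count)` to the Glu count (round-half-up, since whole
#' residues convert). The input object is not modified.
#'
#' @param comp an [ionizable_composition()].
#' @param degree fraction in `[0, 1]` of the pool to convert.
#' @return A new `ionizable_composition` with augmented acidic counts.
#' @export
#' @examples
#' deamidate(collagen_composition(), 0.24)  # +11 Asp, +18 Glu
deamidate <- function(comp, degree) {
  stopifnot(inherits(comp, "ionizable_composition"))
  if (!is.numeric(degree) || length(degree) != 1L || degree < 0 || degree > 1)
    stop("'degree' must be a fraction in [0, 1]", call. = FALSE)
  extra_asp <- round_half_up(degree * comp$asn_count)
  extra_glu <- round_half_up(degree * comp$gln_count)
  out <- comp
  i_asp <- match("Asp", out$groups$name)
  i_glu <- match("Glu", out$groups$name)
  if (is.na(i_asp) || is.na(i_glu))
    stop("composition must carry 'Asp' and 'Glu' classes to deamidate",
         call. = FALSE)
  out$groups$count[i_asp] <- out$groups$count[i_asp] + extra_asp
  out$groups$count[i_glu] <- out$groups$count[i_glu] + extra_glu
  out$asn_count <- comp$asn_count - extra_asp
  out$gln_count <- comp$gln_count - extra_glu
  out$deamidation_degree <- degree
  out
}

#' Net fixed charge of a protein molecule at a given pH
#'
#' Henderson-Hasselbalch expectation of the charge per molecule. Each
#' acidic class contributes `count * 10^(pH-pKa) / (1 + 10^(pH-pKa))`
#' negative charges and each basic class `count / (1 + 10^(pH-pKa))`
#' positive charges, with pKa values corrected internally via
#' [correct_pka()]. The net charge is reported as
#' `n_net = n_positive - n_negative`, so it is positive below the
#' isoelectric point and strictly decreasing in pH.
#'
#' @param comp an [ionizable_composition()].
#' @param pH numeric vector of pH values.
#' @param temperature_C temperature in degC.
#' @param ionic_strength molal-scale ionic strength.
#' @return A data frame of class `charge_state` with columns `pH`,
#'   `n_negative`, `n_positive`, `n_net`.
#' @export
net_charge <- function(comp, pH, temperature_C = 37, ionic_strength = 0.180) {
  stopifnot(inherits(comp, "ionizable_composition"))
  g <- comp$groups
  pka <- correct_pka(g, temperature_C, ionic_strength)
  acid <- g$pair_sign < 0
  n_neg <- vapply(pH, function(p) {
    r <- 10^(p - pka[acid])
    sum(g$count[acid] * r / (1 + r))
  }, numeric(1))
  n_pos <- vapply(pH, function(p) {
    sum(g$count[!acid] / (1 + 10^(p - pka[!acid])))
  }, numeric(1))
  out <- data.frame(pH = pH, n_negative = n_neg, n_positive = n_pos,
                    n_net = n_pos - n_neg)
  class(out) <- c("charge_state", class(out))
  out
}

#' Titration curve of the net fixed charge
#'
#' Evaluates [net_charge()] on a strictly increasing pH grid.
#'
#' @inheritParams net_charge
#' @param pH_grid strictly increasing numeric vector.
#' @return A `charge_state` data frame, one row per grid point.
#' @export
titration_curve <- function(comp, pH_grid, temperature_C = 37,
                            ionic_strength = 0.180) {
  if (length(pH_grid) < 2L || any(diff(pH_grid) <= 0))
    stop("'pH_grid' must be strictly increasing", call. = FALSE)
  net_charge(comp, pH_grid, temperature_C, ionic_strength)
}

#' Isoelectric point by bisection
#'
#' Root of the net-charge curve on the bracket `[1, 13]`, found by
#' bisection to an absolute tolerance of 1e-4 pH units. The net charge must
#' change sign on the bracket.
#'
#' @inheritParams net_charge
#' @param lower,upper search bracket (default `[1, 13]`).
#' @param tol absolute pH tolerance (default `1e-4`).
#' @return The isoelectric pH (numeric scalar).
#' @export
#' @examples
#' find_iep(deamidate(collagen_composition(), 0.24))  # ~5.5
find_iep <- function(comp, temperature_C = 37, ionic_strength = 0.180,
                     lower = 1, upper = 13, tol = 1e-4) {
  f <- function(p) net_charge(comp, p, temperature_C, ionic_strength)$n_net
  f_lo <- f(lower); f_hi <- f(upper)
  if (is.na(f_lo) || is.na(f_hi) || f_lo * f_hi > 0)
    stop("net charge does not change sign on [", lower, ", ", upper, "]",
         call. = FALSE)
  while (upper - lower > tol) {
    mid <- (lower + upper) / 2
    f_mid <- f(mid)
    if (f_mid == 0) return(mid)
    if (f_lo * f_mid < 0) {
      upper <- mid
    } else {
      lower <- mid
      f_lo <- f_mid
    }
  }
  (lower + upper) / 2
}

#' Fixed-charge concentration of a swollen matrix
#'
#' Concentration of net fixed charge carried by the collagen component of a
#' swollen matrix: `c_p = n_net_abs * nu2eq * rho_coll / molar_mass`
#' (mol/cm^3), where `nu2eq` is the collagen volume fraction at equilibrium
#' swelling.
#'
#' @param nu2eq polymer (collagen) volume fraction at equilibrium, in (0, 1).
#' @param rho_coll collagen density, g/cm^3 (default 1.195, the density of
#'   the collagen-only freeze-dried matrix).
#' @param molar_mass collagen molar mass, g/mol (default 3e5).
#' @param n_net_abs magnitude of the net charge per molecule (default 17.6,
#'   the operating-condition value for 24%-deamidated atelocollagen).
#' @return A list of class `fixed_charge_result` with element `c_p`
#'   (mol/cm^3).
#' @export
#' @examples
#' fixed_charge_concentration(0.136)$c_p * 1e8  # ~953-955
fixed_charge_concentration <- function(nu2eq, rho_coll = 1.195,
                                       molar_mass = 3e5, n_net_abs = 17.6) {
  if (any(nu2eq <= 0) || any(nu2eq >= 1))
    stop("'nu2eq' must lie in (0, 1)", call. = FALSE)
  if (rho_coll <= 0 || molar_mass <= 0)
    stop("densities and molar mass must be positive", call. = FALSE)
  structure(list(c_p = n_net_abs * nu2eq * rho_coll / molar_mass),
            class = "fixed_charge_result")
}
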