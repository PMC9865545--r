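#' Extinction coefficients for the two-wavelength quantification
#'
#' Absorptivities of TA and CHDG at the two monitoring wavelengths
#' (325 nm, where TA dominates, and 260 nm, where CHDG dominates),
#' per unit path length and per unit concentration. Any concentration
#' unit may be used (mol/L or mg/mL) as long as it is used consistently.
#'
#' The shipped defaults are synthetic placeholder values shaped after the
#' qualitative spectra of the two compounds (TA absorbs at both
#' wavelengths; CHDG is dominated by its 260 nm band with almost no
#' 325 nm absorbance); every algorithm in this module is ratio-based or
#' round-trip and does not depend on the specific numbers.
#'
#' @param eps_ta_325,eps_ta_260 TA absorptivities at 325/260 nm.
#' @param eps_chdg_325,eps_chdg_260 CHDG absorptivities at 325/260 nm.
#' @param path_length optical path, cm (default 1).
#' @param conc_unit label for the concentration unit (default
#'   `"mg_per_mL"`).
#' @return An object of class `extinction_set`.
#' @export
extinction_set <- function(eps_ta_325 = 30, eps_ta_260 = 18,
                           eps_chdg_325 = 0.5, eps_chdg_260 = 38,
                           path_length = 1, conc_unit = "mg_per_mL") {
  eps <- c(eps_ta_325, eps_ta_260, eps_chdg_325, eps_chdg_260)
  if (any(eps < 0)) stop("extinction coefficients must be >= 0",
                         call. = FALSE)
  if (eps_ta_325 <= 0 || eps_chdg_260 <= 0)
    stop("eps_ta_325 and eps_chdg_260 must be positive", call. = FALSE)
  if (path_length <= 0) stop("'path_length' must be positive", call. = FALSE)
  structure(list(eps_ta_325 = eps_ta_325, eps_ta_260 = eps_ta_260,
                 eps_chdg_325 = eps_chdg_325, eps_chdg_260 = eps_chdg_260,
                 path_length = path_length, conc_unit = conc_unit),
            class = "extinction_set")
}

#' Background-referenced absorbance reading pair
#'
#' A pair of absorbances at 325 and 260 nm, referenced against the
#' PBS-HTAB blank. Small negative values arising from blank subtraction
#' noise are clipped to zero and flagged in the attribute `clipped`.
#'
#' @param a325,a260 absorbance values (vectorized).
#' @return A data frame of class `spectrum_reading`.
#' @export
spectrum_reading <- function(a325, a260) {
  clipped <- a325 < 0 | a260 < 0
  if (any(clipped))
    warning(sum(clipped), " negative absorbance(s) clipped to 0",
            call. = FALSE)
  out <- data.frame(a325 = pmax(a325, 0), a260 = pmax(a260, 0))
  attr(out, "clipped") <- clipped
  class(out) <- c("spectrum_reading", class(out))
  out
}

#' Forward Beer-Lambert prediction of a two-component reading
#'
#' `A_lambda = path * (eps_TA,lambda * c_TA + eps_CHDG,lambda * c_CHDG)`
#' at both monitoring wavelengths.
#'
#' @param c_ta,c_chdg concentrations (>= 0), in the unit of `eps`.
#' @param eps an [extinction_set()].
#' @return A [spectrum_reading()].
#' @export
predict_reading <- function(c_ta, c_chdg, eps = extinction_set()) {
  stopifnot(inherits(eps, "extinction_set"))
  if (any(c_ta < 0) || any(c_chdg < 0))
    stop("concentrations must be >= 0", call. = FALSE)
  spectrum_reading(
    a325 = eps$path_length * (eps$eps_ta_325 * c_ta + eps$eps_chdg_325 * c_chdg),
    a260 = eps$path_length * (eps$eps_ta_260 * c_ta + eps$eps_chdg_260 * c_chdg))
}

# extinction-corrected A325/A260 ratio: the 325 nm absorbance in units of
# the pure-TA response over the 260 nm absorbance in units of the
# pure-CHDG response. Depends only on the composition ratio, not on the
# overall dilution.
corrected_ratio <- function(a325, a260, eps) {
  (a325 / eps$eps_ta_325) / (a260 / eps$eps_chdg_260)
}

#' Ratio matrix of expected composition signatures
#'
#' Tabulates, for every (TA, CHDG) composition on the two concentration
#' grids, the extinction-corrected A325/A260 ratio predicted by the
#' Beer-Lambert forward model. Because the corrected ratio depends only on
#' the TA:CHDG concentration ratio, the matrix is invariant to a common
#' scaling of both grids; cells with zero 260 nm absorbance are flagged
#' `NA` (unusable).
#'
#' @param ta_grid,chdg_grid strictly increasing concentration grids.
#' @param eps an [extinction_set()].
#' @return An object of class `ratio_matrix`: list with `ta_grid`,
#'   `chdg_grid`, `expected_ratio` (rows = TA, columns = CHDG).
#' @export
build_ratio_matrix <- function(ta_grid, chdg_grid, eps = extinction_set()) {
  if (!length(ta_grid) || !length(chdg_grid))
    stop("grids must be non-empty", call. = FALSE)
  if (any(diff(ta_grid) <= 0) || any(diff(chdg_grid) <= 0))
    stop("grids must be strictly increasing", call. = FALSE)
  m <- outer(ta_grid, chdg_grid, function(ta, ch) {
    r <- predict_reading(ta, ch, eps)
    ifelse(r$a260 > 0, corrected_ratio(r$a325, r$a260, eps), NA_real_)
  })
  dimnames(m) <- list(ta = signif(ta_grid, 6), chdg = signif(chdg_grid, 6))
  structure(list(ta_grid = ta_grid, chdg_grid = chdg_grid,
                 expected_ratio = m, eps = eps),
            class = "ratio_matrix")
}

#' Default geometric concentration grid
#'
#' Geometric grid of 25 points spanning two decades, the default
#' resolution of the ratio matrix (composition ratios scale
#' multiplicatively).
#'
#' @param from,to grid end points (defaults 0.01 to 1).
#' @param n number of points (default 25).
#' @return Strictly increasing numeric vector.
#' @export
geometric_grid <- function(from = 0.01, to = 1, n = 25) {
  exp(seq(log(from), log(to), length.out = n))
}

#' Match a reading to the nearest ratio-matrix composition
#'
#' Finds the matrix cell whose expected corrected ratio is closest to the
#' observed one; ties are broken toward the lower-TA cell (the
#' conservative release estimate).
#'
#' @param reading a single-row [spectrum_reading()] with `a260 > 0`.
#' @param matrix a [build_ratio_matrix()] result.
#' @return A list with `ta_over_chdg` (concentration ratio of the matched
#'   cell), `i`, `j` (cell indices), and `expected_ratio`.
#' @export
match_composition <- function(reading, matrix) {
  stopifnot(inherits(matrix, "ratio_matrix"))
  if (nrow(reading) != 1L)
    stop("'reading' must be a single reading", call. = FALSE)
  if (reading$a260 <= 0)
    stop("cannot classify a reading with A260 = 0", call. = FALSE)
  obs <- corrected_ratio(reading$a325, reading$a260, matrix$eps)
  d <- abs(matrix$expected_ratio - obs)
  best <- min(d, na.rm = TRUE)
  hits <- which(d - best <= best * 1e-12 + 1e-15, arr.ind = TRUE)
  # tie-break toward the lower-TA cell, then lower CHDG index
  hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
  i <- hits[1, 1]; j <- hits[1, 2]
  list(ta_over_chdg = matrix$ta_grid[i] / matrix$chdg_grid[j],
       i = unname(i), j = unname(j),
       expected_ratio = matrix$expected_ratio[i, j])
}

#' Solve two-component concentrations from one reading
#'
#' Direct inversion of the 2x2 Beer-Lambert system at 325 and 260 nm.
#'
#' @param reading a [spectrum_reading()] (vectorized over rows).
#' @param eps an [extinction_set()].
#' @return Data frame with columns `c_ta`, `c_chdg` (negative solutions
#'   clipped to 0 with a warning).
#' @export
solve_concentrations <- function(reading, eps = extinction_set()) {
  stopifnot(inherits(eps, "extinction_set"))
  E <- matrix(c(eps$eps_ta_325, eps$eps_chdg_325,
                eps$eps_ta_260, eps$eps_chdg_260),
              nrow = 2, byrow = TRUE) * eps$path_length
  sol <- t(solve(E, t(cbind(reading$a325, reading$a260))))
  if (any(sol < 0))
    warning("negative concentration solution(s) clipped to 0",
            call. = FALSE)
  data.frame(c_ta = pmax(sol[, 1], 0), c_chdg = pmax(sol[, 2], 0))
}

#' Calibrate dilution series and quantify an unknown
#'
#' Given a dilution series of standards at a fixed TA:CHDG composition
#' ratio, fits an ordinary least-squares calibration line (absorbance
#' against TA concentration) at each wavelength, then inverts each line at
#' the unknown's absorbances. Because the composition ratio is fixed, each
#' wavelength yields an independent TA (and hence CHDG) estimate; the
#' relative discrepancy between the two is reported as a consistency
#' check.
#'
#' @param standards data frame with columns `c_ta`, `c_chdg` (known
#'   concentrations at a fixed ratio, >= 3 rows), `a325`, `a260`.
#' @param unknown a single-row [spectrum_reading()] for the sample to
#'   quantify.
#' @return A list of class `calibration_result`: `lines` (data frame of
#'   per-wavelength slope, intercept, r_squared), `c_ta`, `c_chdg`
#'   (averaged estimates), `consistency` (relative discrepancy between the
#'   two wavelength estimates).
#' @export
calibrate_and_quantify <- function(standards, unknown) {
  need <- c("c_ta", "c_chdg", "a325", "a260")
  if (!all(need %in% names(standards)))
    stop("'standards' must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (nrow(standards) < 3)
    stop("need at least 3 dilution points", call. = FALSE)
  ratios <- standards$c_chdg / standards$c_ta
  if (max(ratios) - min(ratios) > 1e-6 * max(ratios))
    stop("standards must share a fixed TA:CHDG ratio", call. = FALSE)
  r <- ratios[1]
  fit_line <- function(a) {
    m <- stats::lm(a ~ standards$c_ta)
    # suppress the zero-residual note: noiseless standards are legitimate
    r2 <- suppressWarnings(summary(m)$r.squared)
    c(intercept = unname(stats::coef(m)[1]),
      slope = unname(stats::coef(m)[2]),
      r_squared = r2)
  }
  l325 <- fit_line(standards$a325)
  l260 <- fit_line(standards$a260)
  if (l325["slope"] <= 0 || l260["slope"] <= 0)
    stop("calibration slope non-positive", call. = FALSE)
  est325 <- (unknown$a325 - l325["intercept"]) / l325["slope"]
  est260 <- (unknown$a260 - l260["intercept"]) / l260["slope"]
  c_ta <- unname((est325 + est260) / 2)
  structure(list(
    lines = data.frame(wavelength = c(325, 260),
                       intercept = c(l325[1], l260[1]),
                       slope = c(l325[2], l260[2]),
                       r_squared = c(l325[3], l260[3])),
    c_ta = c_ta, c_chdg = c_ta * r,
    consistency = unname(abs(est325 - est260) /
                           max(abs(c_ta), .Machine$double.eps))),
    class = "calibration_result")
}

#' Fractional release from a measured concentration
#'
#' `fraction = c_t * vessel_volume * 1000 / loaded_mass` for a
#' concentration in mg/mL (or after conversion by `molar_mass` for
#' mol/L), clipped to `[0, 1]` with a warning above 1.
#'
#' @param c_t concentration at time t (mg/mL, or mol/L if `molar_mass`
#'   is supplied).
#' @param loaded_mass mass initially loaded in the dry matrix, mg (> 0).
#' @param vessel_volume release-vessel volume, L (default 1).
#' @param molar_mass if supplied, `c_t` is mol/L and is converted with
#'   this molar mass (g/mol).
#' @return Fractional release in `[0, 1]`.
#' @export
fraction_released <- function(c_t, loaded_mass, vessel_volume = 1,
                              molar_mass = NULL) {
  if (loaded_mass <= 0) stop("'loaded_mass' must be > 0", call. = FALSE)
  if (any(c_t < 0)) stop("concentrations must be >= 0", call. = FALSE)
  mg_per_mL <- if (is.null(molar_mass)) c_t else c_t * molar_mass  # g/L = mg/mL
  frac <- mg_per_mL * vessel_volume * 1000 / loaded_mass
  if (any(frac > 1))
    warning("computed release fraction exceeds 1; clipping", call. = FALSE)
  pmin(pmax(frac, 0), 1)
}
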