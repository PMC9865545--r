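---
title: "Charge, swelling and release analytics for antimicrobial-loaded collagen matrices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Charge, swelling and release analytics for antimicrobial-loaded collagen matrices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(colkin)
```

`colkin` analyzes freeze-dried atelocollagen type I matrices loaded with two
antimicrobials -- tannic acid (TA) and chlorhexidine digluconate (CHDG) --
released into phosphate-buffered saline with micellar HTAB carriers at
pH 7.40 and 37 °C. It chains four pieces of physical chemistry: a
protein-titration model for the net fixed charge of collagen, a
Donnan/Flory treatment of equilibrium swelling that yields the network
crosslink density, a two-mechanism (Fickian vs. Case II) description of
fractional release from a cylinder, and a two-wavelength Beer--Lambert
scheme for quantifying the two analytes simultaneously. A synthetic-data
module emulates the corresponding wet-lab measurements so every stage is
testable end to end.

## 1. Net fixed charge and isoelectric point

Each ionizable residue class contributes its Henderson--Hasselbalch
expectation. With $N_i$ acidic groups (Asp, Glu, C-terminal carboxyls) of
corrected acidity exponent $\mathrm{p}K_{a,i}$ and $N_j$ basic groups
(His, Lys, Arg, N-terminal amines),

$$
N_\mathrm{net}(\mathrm{pH}) \;=\;
\sum_j \frac{N_j}{1 + 10^{\,\mathrm{pH} - \mathrm{p}K_{a,j}}}
\;-\;
\sum_i N_i\,\frac{10^{\,\mathrm{pH} - \mathrm{p}K_{a,i}}}
                 {1 + 10^{\,\mathrm{pH} - \mathrm{p}K_{a,i}}},
$$

positive below the isoelectric point (IEP) and strictly decreasing in pH.
The sign convention is "positive = net cationic"; some treatments report
the negative-minus-positive difference instead, which only flips the curve.

Reference pKa values hold at 25 °C and zero ionic strength and are
corrected in two steps:

* **Temperature** (van't Hoff): $\Delta\mathrm{p}K_a =
  \frac{\Delta H_\mathrm{ion}}{R\ln 10}\left(\frac1T - \frac1{298.15}\right)$
  with standard ionization enthalpies (large for ammonium-type groups,
  ~1--4 kJ mol$^{-1}$ for carboxyls).
* **Ionic strength** (Davies form): $\Delta\mathrm{p}K_a =
  Z \cdot 2A(T)\left(\frac{\sqrt I}{1+\sqrt I} - 0.3\,I\right)$, where
  $Z=-1$ for --COOH/--COO$^-$ pairs and $+1$ for --NH$_3^+$/--NH$_2$
  pairs. Both corrections vanish at 25 °C and $I=0$.

The default composition (`collagen_composition()`) carries the bovine
atelocollagen counts Asp 90, Glu 150, C-terminal Pro 3, His 14, Arg 162,
Lys 89, N-terminal Gly 3. Alkaline extraction partially deamidates
Asn/Gln; `deamidate()` converts a fraction of the Asn 46 / Gln 75 pool
with round-half-up integer increments (whole residues convert), so the
operating 24% adds 11 Asp and 18 Glu. The pool sizes are the smallest
integers consistent with those increments under that rounding.

**Calibration.** The exact per-residue pKa set for this collagen is not
tabulated anywhere we can consult, so the shipped table uses standard
protein values adjusted within their literature ranges (Glu 4.30,
N-terminal $\alpha$-amino 8.60, all others at textbook midpoints) until
three independent anchors hold simultaneously under the operating
conditions (pH 7.40, $I = 0.180$, 37 °C): net charge magnitude 17.6 for
the 24%-deamidated molecule, IEP 5.5 deamidated, and IEP above 8 without
deamidation. Every entry is exposed in the returned object (and as a CSV
fixture) for overriding. Because the anchors are the only ground truth,
agreement of the *shape* of the titration curve away from them should not
be over-interpreted.

```{r charge}
de <- deamidate(collagen_composition(), 0.24)
net_charge(de, 7.40)
find_iep(de)
```

The IEP solver is plain bisection on pH [1, 13] to $10^{-4}$ pH units:
the curve is strictly monotone, so bracketing is guaranteed whenever the
composition carries both acidic and basic groups.

## 2. Swelling, Donnan equilibrium and crosslink density

Gravimetric uptake $Q_w$ (swollen mass / dry mass) is first stripped of
the buffer held by capillarity in the macro-pores:
`capillary_correct()` subtracts `pore_volume_per_gram * rho_buffer` and
floors at 1 g/g (the physical lower bound). The pore volume comes from
ethanol pycnometry; for the collagen-only matrix it is ~95.6 cm$^3$/g,
which is why raw plateaus near 111 g/g reduce to a true network uptake of
6.80 g/g. The buffer density at 37 °C (1.093 g/cm$^3$) is obtained by
scaling the 20 °C measurement (1.098) by the ratio of Kell-equation water
densities.

Volume conversion distinguishes two limiting cases, because the dry-solid
composition at equilibrium is unknown in mid-release:

* *released* (both drugs essentially gone): the dry solid is collagen,
  $Q_{v,\mathrm{coll}} = 1 + (Q_w - 1)\rho_\mathrm{coll}/\rho_\mathrm{buf}$
  and $\nu_{2eq} = 1/Q_{v,\mathrm{coll}}$;
* *loaded* (nothing released):
  $Q_{v,\mathrm{matrix}} = 1 + (Q_w - 1)\rho_\mathrm{matrix}/\rho_\mathrm{buf}$,
  and the collagen-referenced ratio uses the composition mass fractions
  (volume-additive convention). That convention recovers the tabulated
  loaded-case collagen ratios only to ~2% -- the original reduction used
  unavailable auxiliary expressions -- so for loaded-case reproduction the
  tabulated $\nu_{2eq}$ is treated as authoritative
  (`nu2eq_source = "reference"`).

The fixed-charge concentration of the swollen network is
$c_p = |N_\mathrm{net}|\,\nu_{2eq}\,\rho_\mathrm{coll}/M$ (mol cm$^{-3}$,
$M = 3\times10^5$ g mol$^{-1}$), and Donnan equilibrium against an
equivalent 1:1 electrolyte of parameter $c_e$ gives the excess mobile-ion
concentration $\Delta c = \sqrt{c_p^2 + 4c_e^2} - 2c_e$. The PBS
accounting (10 mM phosphate split 1:1.6 between H$_2$PO$_4^-$ and
HPO$_4^{2-}$, sodium counted at twice the total phosphate with a chloride
makeweight, 154 mM NaCl fully dissociated) yields $I = 0.180$ and
$c_e = 0.090$ M $= 9\times10^{-5}$ mol cm$^{-3}$. The sodium convention
is reverse-engineered from the phosphate-subsystem value 0.026 and is a
documented, overridable choice (`sodium_per_phosphate`).

Crosslink density follows the swelling relation for polyelectrolyte
networks formed in solution at polymer fraction $\nu_{20}$:

$$
DC \;=\; \frac{V_1\,\Delta c - \left[\ln(1-\nu_{2eq}) + \nu_{2eq} +
\chi_1\nu_{2eq}^2\right]}
{V_1\,\nu_{20}\left[(\nu_{2eq}/\nu_{20})^{1/3} -
\nu_{2eq}/(2\nu_{20})\right]},
$$

which collapses onto the bulk-network (Flory) form at $\nu_{20}=1$ (a
property test asserts the reduction to $10^{-12}$). Defaults:
$\chi_1 = 0.49$ (collagen--water), $V_1 = 18.07$ cm$^3$ mol$^{-1}$ (water
near 37 °C; not stated in the source tables but verified to reproduce
them), $\nu_{20} = 0.20$ (collagen fraction of fresh hide). All
concentrations are mol cm$^{-3}$ internally; mol L$^{-1}$ appears only at
interfaces (conversion $\times 10^{-3}$).

```{r table}
tb <- run_crosslink_table(collagen_swelling_fixture("released"))
tb[, c("system", "nu2eq", "cp_1e8", "delta_c_1e7", "dc_1e5", "within_tol")]
```

Verification compares each computed column against the tabulated one at
1% relative tolerance after deducting half of one printed unit (the
tables round $\nu_{2eq}$ to 3 decimals and $\Delta c$ to one); the DC
column is additionally compared against its recomputation from the
rounded intermediates, because that is how the tabulated DC values were
produced (the sensitivity of the logarithmic bracket to the third decimal
of $\nu_{2eq}$ otherwise inflates two rows to ~1.2%).

## 3. Release kinetics from a cylindrical matrix

Release through the lateral surface of a wax-capped cylinder is treated
as one-dimensional radial transport. Two ideal mechanisms bracket the
behavior, both parameterized by a reduced diffusivity $D/a^2$
(min$^{-1}$) whose defaults encode the observed equilibrium times:
1/1440 for TA (24 h) and 1/4320 for CHDG (72 h).

* **Fickian** (`fickian_fraction()`): the three-term small-time expansion
  $M_t/M_\infty = \tfrac{4}{\sqrt\pi}x^{1/2} - x -
  \tfrac{1}{3\sqrt\pi}x^{3/2}$, $x = (D/a^2)t$, valid to 60% release
  (beyond that the caller is warned, not stopped). A finite-difference
  solution of the radial diffusion equation, written independently as a
  test oracle, agrees within 1% over the valid window.
* **Case II** (`case2_fraction()`): relaxation-controlled front movement,
  $M_t/M_\infty = 2x - x^2$, the cylinder ($N=2$) instance of the shape
  family $1-(1-x)^N$.

`fit_power_law()` fits the Korsmeyer--Peppas law $M_t/M_\infty = k\,t^n$
by Levenberg--Marquardt least squares on *untransformed* fractions
(a log-log fit would overweight the early points and shift $n$), after
truncating to the first 60% of release; at least 5 points are required.
`reference_power_law()` reproduces the reference constants by sampling
the exact forward models on a uniform 1-min grid from $t=1$ to the 60%
crossing (~140 min Fickian, ~529 min Case II). The original sampling grid
is unstated; the 1-min uniform grid is this package's choice, and the
fitted constants ($k = 6.62\times10^{-2}$, $n=0.448$ Fickian;
$k=2.339\times10^{-3}$, $n=0.8871$ Case II for TA) fall within the
reported standard errors of the tabulated values
($6.569\pm0.087\times10^{-2}$, $0.4497\pm0.0030$; $2.34\pm0.02\times
10^{-3}$, $0.88703\pm0.00167$). A consistency law ties the two analytes:
$k$ scales as $(D/a^2)^n$, so the TA/CHDG ratio of fitted $k$ equals
$3^n$ to 0.5%.

`decompose_release()` writes an observed first-60% series as
$a\,k_F t^{n_F} + b\,k_{II} t^{n_{II}}$ and solves for $(a,b)$ by
non-negative least squares -- non-negativity because the weights are
mechanism shares, with no sum constraint since the references are
normalized curves, not the sample's. The Case II percentage is reported
as $100\,b/(a+b)$ by default; a time-integrated estimator (share of the
area under the fitted sum) is also returned because the original
percentage definition is ambiguous. `classify_mechanism()` applies the
cylinder exponent limits: $n \le 0.45$ Fickian, $n$ within $\pm0.01$ of
0.89 Case II, above 0.90 super-Case II, anomalous between (slab limits
0.5/1.0).

```{r kinetics}
reference_power_law("TA", "fickian")
g <- gen_release_series(0.3, 0.7, generator_config(seed = 7), "TA")
decompose_release(g$series)
```

## 4. Two-wavelength quantification

TA and CHDG absorb at 325 and 260 nm with strongly different weights, so
a reading pair $(A_{325}, A_{260})$ referenced against the PBS--HTAB
blank determines both concentrations. The ratio-matrix algorithm mirrors
the bench procedure:

1. `build_ratio_matrix()` tabulates, over geometric concentration grids
   (25 points across two decades by default -- composition ratios scale
   multiplicatively), the extinction-corrected ratio
   $(A_{325}/\varepsilon_{TA,325})/(A_{260}/\varepsilon_{CHDG,260})$,
   which depends only on the TA:CHDG ratio;
2. `match_composition()` finds the cell nearest the observed corrected
   ratio (ties break toward lower TA, the conservative release estimate);
3. `calibrate_and_quantify()` fits per-wavelength calibration lines
   through a fixed-ratio dilution series and inverts them at the unknown,
   reporting the between-wavelength discrepancy as a consistency check;
   `solve_concentrations()` is the direct 2x2 Beer--Lambert inversion.

The shipped extinction defaults are synthetic placeholders (the measured
coefficients are not published); they encode only the qualitative shape
-- TA absorbs at both wavelengths, CHDG essentially only at 260 nm -- and
every test of this module is a ratio or round-trip property that holds
for any valid coefficient set. Negative absorbances from blank
subtraction are clipped to zero and flagged. `fraction_released()`
converts concentration to fractional release against the loaded mass in
the 1 L vessel, clipping at 1 with a warning.

## 5. Synthetic data: what it emulates and what it does not

The generators are pure functions of (parameters, seed), with the seed a
mandatory argument and no hidden global state.

* `gen_release_series()`: convex combinations of the two forward models,
  multiplicative Gaussian noise (RSD 10% by default, the dissolution
  protocol's bound) truncated at $\pm3\sigma$, cumulative-max
  monotonization per replicate (release is physically non-decreasing),
  clipping to [0, 1], triplicate replicates, sampled on the dissolution
  schedule (5-min steps to 30 min, then 15-min steps to 660 min).
  Weight presets per matrix composition interpret the reported mechanism
  shares (>90% Case II for binary TA matrices, 63--76% for ternary TA,
  64--72% for CHDG) and land the 660-min fractions in the observed
  0.7--0.9 (TA) and 0.4--0.6 (CHDG) ranges.
* `gen_swelling_series()`: saturating-exponential approach to the
  equilibrium uptake (rate 0.06 min$^{-1}$, most of the rise inside
  50 min) plus the constant capillary term, on the weighing schedule with
  a 24 h equilibrium point, 15% RSD noise.
* `gen_spectrum_readings()`: fractions to vessel concentrations to
  Beer--Lambert absorbances, 10% RSD noise.

What passing these tests shows is that the *algorithms* invert their own
forward models at the stated noise levels. Real matrices add features the
generators deliberately omit: matrix erosion and disintegration (the
collagen-only sponge breaks apart after ~2 h), drug--drug complexation,
micellar solubilization limits, baseline drift and turbidity in the
spectra, and non-stationary noise. Agreement on synthetic data is
therefore a correctness check, not a validation against biology.

## 6. Numerical choices and degenerate inputs

* Bisection (IEP): fixed bracket [1, 13], tolerance $10^{-4}$ pH;
  errors if the curve does not change sign.
* Power-law fitting: start values $k = f_1/\sqrt{t_1}$, $n = 0.5$;
  non-convergence raises an error carrying the optimizer message.
  Degenerate (constant) series are rejected before decomposition.
* NNLS weights: exact zeros are legitimate outputs (pure-mechanism
  series); the percentage denominators guard against the all-zero case.
* The Bray--Merrill denominator turns non-positive once
  $\nu_{2eq} \gtrsim 2.83\,\nu_{20}$; this raises a diagnostic error
  rather than returning a negative density.
* Uptake floors at 1 g/g after capillary correction; fractions clip to
  [0, 1] with warnings, never silently.
* Problem sizes: reference fits use 139 and 529 grid points; the
  finite-difference oracle uses a 201-point radial grid with explicit
  time steps of $5\times10^{-6}$; recovery loops use 20 seeds and
  100-replicate noise studies. These sizes make the whole suite run in a
  few seconds while keeping Monte Carlo error well inside the asserted
  tolerances.

## 7. Known limitations

* The pKa table is anchor-calibrated, not residue-resolved; charge
  regulation, microenvironment shifts, and hydroxyl ionization (Tyr, Ser,
  Thr) are out of scope.
* The loaded-case volume convention carries a documented ~2% residual
  against the tabulated collagen ratios.
* Extinction coefficients are synthetic placeholders; absolute
  concentrations from the spectra module are only as good as the
  user-supplied coefficients.
* The Fickian model is the small-time expansion only; nothing beyond 60%
  release is modeled, and erosion-front dynamics are not attempted.
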