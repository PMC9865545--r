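# colkin

Physical-chemistry analytics for freeze-dried collagen wound-dressing
matrices loaded with two antimicrobials: tannic acid (TA) and
chlorhexidine digluconate (CHDG). The package is for formulation and
drug-delivery scientists who characterize such matrices by equilibrium
swelling, in vitro dissolution, and UV--VIS spectroscopy, and who want the
whole reduction chain -- from raw gravimetric and absorbance readings to
crosslink densities and transport-mechanism shares -- as tested,
reproducible code.

Four connected models sit at its core:

* **Protein charge state.** The net fixed charge of an atelocollagen
  type I molecule from its ionizable residue counts via
  Henderson--Hasselbalch sums, with van't Hoff temperature and
  Davies ionic-strength pKa corrections and an Asn/Gln deamidation
  adjustment; the isoelectric point (IEP) as the root of the titration
  curve. Under operating conditions (pH 7.40, I = 0.180, 37 °C) the
  24%-deamidated molecule carries |N_net| = 17.6 and has IEP 5.5.
* **Swelling → crosslink density.** Capillary-corrected uptake Q_w to
  polymer volume fraction ν_2eq, fixed-charge concentration
  c_p = |N_net|·ν_2eq·ρ_coll/M, Donnan excess
  Δc = (c_p² + 4c_e²)^½ − 2c_e, and the degree of crosslinking DC from
  the Flory or Bray--Merrill/Ofner--Bubnis swelling relation
  (χ₁ = 0.49, V₁ = 18.07 cm³/mol, ν₂₀ = 0.20).
* **Release kinetics.** Fickian (small-time cylinder expansion) and
  Case II (relaxational, 2x − x²) forward models, Korsmeyer--Peppas
  fitting M_t/M_∞ = k·tⁿ on the first 60% of release, non-negative
  least-squares decomposition of observed release into Fickian/Case II
  weights, and mechanism classification by the cylinder exponent limits
  0.45/0.89.
* **Two-wavelength quantification.** Beer--Lambert forward model at
  325 nm (TA) and 260 nm (CHDG), a ratio-matrix composition matcher,
  fixed-ratio calibration lines, direct 2×2 inversion, and conversion to
  fractional release.

A synthetic-data module (`gen_release_series()`, `gen_swelling_series()`,
`gen_spectrum_readings()`) generates all of these inputs with the noise
structure of the corresponding protocols (10% RSD release/absorbance,
15% RSD swelling, triplicates), so the pipeline is fully testable without
laboratory data.

## Worked example

```r
library(colkin)

# Charge state of 24%-deamidated atelocollagen at operating conditions
de <- deamidate(collagen_composition(), 0.24)
net_charge(de, 7.40)
#>    pH n_negative n_positive     n_net
#> 1 7.4   271.9099   254.3145 -17.59541
find_iep(de)
#> [1] 5.4948
```

The molecule is net negative by 17.6 elementary charges at pH 7.40 and
isoelectric at pH 5.5 -- which is why the cationic chlorhexidine binds
electrostatically to the swollen network.

```r
# Full swelling -> crosslink chain for the seven studied matrices
tb <- run_crosslink_table(collagen_swelling_fixture("released"))
tb[c(1, 4), c("system", "q_w", "nu2eq", "cp_1e8", "delta_c_1e7", "dc_1e5")]
#>              system  q_w  nu2eq cp_1e8 delta_c_1e7 dc_1e5
#> 1          Collagen 6.80 0.1362  954.7       2.528  57.89
#> 4 Collagen-TA (15%) 4.11 0.2272 1592.8       7.028 305.80
```

Starting only from the equilibrium uptakes (6.80 and 4.11 g/g) and
densities, the chain returns the fixed-charge concentration (×10⁻⁸
mol/cm³), Donnan excess (×10⁻⁷) and crosslink density (×10⁻⁵): the
collagen-only sponge is essentially uncrosslinked (DC ≈ 58×10⁻⁵ mol/cm³)
while 15% TA quintuples the junction density (≈ 306×10⁻⁵).

```r
# Reference transport fits and a synthetic release decomposition
reference_power_law("TA", "fickian")
#> Power-law fit (first60, 139 pts): k = 0.06621 +/- 0.00031, n = 0.4480 +/- 0.0010, R2 = 0.99956

g <- gen_release_series(0.3, 0.7, generator_config(seed = 7), "TA")
decompose_release(g$series)
#> Release decomposition: a (Fickian) = 0.326, b (Case II) = 0.688, Case II share 67.9% (integrated 43.6%)
classify_mechanism(fit_power_law(g$series)$n)
#> [1] "anomalous"
```

A noisy 30/70 Fickian/Case II mixture is decomposed back to a ~68%
Case II share, and its fitted exponent (n ≈ 0.62, between the cylinder
limits 0.45 and 0.89) classifies the transport as anomalous -- release
controlled jointly by diffusion and network relaxation.

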