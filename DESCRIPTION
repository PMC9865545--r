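Package: colkin
Title: Charge State, Swelling Thermodynamics and Release Kinetics of
    Antimicrobial-Loaded Collagen Matrices
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for freeze-dried atelocollagen matrices loaded
    with tannic acid (TA) and chlorhexidine digluconate (CHDG). Computes the
    pH-dependent net fixed charge and isoelectric point of atelocollagen from
    its ionizable residue composition (with temperature and ionic-strength
    pKa corrections and an Asn/Gln deamidation adjustment), converts
    gravimetric buffer-uptake measurements into polymer volume fractions and
    estimates network crosslink density via Donnan equilibrium and the
    Flory and Bray-Merrill/Ofner-Bubnis swelling relations, forward-simulates
    and decomposes fractional drug release from cylindrical matrices into
    Fickian and Case II (relaxational) contributions with Korsmeyer-Peppas
    power-law fitting, and implements a two-wavelength Beer-Lambert
    ratio-matrix algorithm for simultaneous UV-VIS quantification of the two
    released antimicrobials. A synthetic-data module generates uptake,
    release, and paired-absorbance series with realistic noise so the whole
    pipeline is testable without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
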