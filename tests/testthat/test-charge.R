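# net-charge model: pKa corrections, deamidation, titration, IEP, c_p

test_that("pKa corrections vanish at reference conditions and follow the pair sign", {
  comp <- collagen_composition()
  g <- comp$groups
  expect_equal(correct_pka(g, 25, 0), g$pka_ref, tolerance = 1e-12)

  corrected <- correct_pka(g, 37, 0.180)
  # ionic-strength term alone lowers acidic and raises basic pKa values
  i_only <- correct_pka(transform(g, ionization_enthalpy = 0), 37, 0.180)
  expect_true(all((i_only - g$pka_ref) * g$pair_sign > 0))
  # van't Hoff term alone lowers every pKa on warming (positive enthalpies)
  t_only <- correct_pka(g[g$ionization_enthalpy > 0, ], 37, 0)
  expect_true(all(t_only < g$pka_ref[g$ionization_enthalpy > 0]))

  # independent arithmetic for the Glu class at the operating conditions
  A37 <- 0.5092 + (37 - 25) / (50 - 25) * (0.5336 - 0.5092)
  f <- sqrt(0.18) / (1 + sqrt(0.18)) - 0.3 * 0.18
  vh <- 1000 / (8.31446 * log(10)) * (1 / 310.15 - 1 / 298.15)
  glu_expected <- 4.30 + vh - 2 * A37 * f
  expect_equal(corrected[g$name == "Glu"], glu_expected, tolerance = 1e-10)

  expect_error(correct_pka(g, 37, -0.1), "ionic strength")
  expect_error(correct_pka(g, 120, 0.1), "temperature")
})

test_that("deamidation augments the acidic counts by round-half-up and keeps the input intact", {
  comp <- collagen_composition()
  de <- deamidate(comp, 0.24)
  count_of <- function(x, nm) x$groups$count[x$groups$name == nm]
  expect_equal(count_of(de, "Asp") - count_of(comp, "Asp"), 11)
  expect_equal(count_of(de, "Glu") - count_of(comp, "Glu"), 18)
  expect_equal(de$deamidation_degree, 0.24)
  # original untouched
  expect_equal(count_of(comp, "Asp"), 90)

  expect_equal(deamidate(comp, 0)$groups$count, comp$groups$count)

  small <- ionizable_composition(collagen_composition()$groups,
                                 asn_count = 10L, gln_count = 10L)
  full <- deamidate(small, 1.0)
  expect_equal(count_of(full, "Asp") - 90, 10)
  expect_equal(count_of(full, "Glu") - 150, 10)
  expect_equal(full$asn_count, 0)

  # round-half-up, not banker's rounding: 0.5 * 5 = 2.5 -> 3
  half <- ionizable_composition(collagen_composition()$groups,
                                asn_count = 5L, gln_count = 0L)
  expect_equal(count_of(deamidate(half, 0.5), "Asp") - 90, 3)

  expect_error(deamidate(comp, -0.1), "fraction")
  expect_error(deamidate(comp, 1.2), "fraction")
})

test_that("net charge matches per-group enumeration and has the counting asymptotes", {
  toy <- ionizable_composition(rbind(
    ionizable_group("acid", 3L, 4.1, -1, 1500),
    ionizable_group("base", 5L, 9.7, +1, 40000)))
  for (pH in c(2.0, 4.1, 6.5, 7.4, 9.7, 11.0)) {
    pk <- correct_pka(toy$groups, 37, 0.18)
    expect_equal(net_charge(toy, pH, 37, 0.18)$n_net,
                 enumerate_net_charge(toy$groups$count, pk,
                                      toy$groups$pair_sign, pH),
                 tolerance = 1e-12)
  }
  # asymptotes: all bases protonated at low pH, all acids ionized at high pH
  expect_equal(net_charge(toy, -6)$n_net, 5, tolerance = 1e-6)
  expect_equal(net_charge(toy, 20)$n_net, -3, tolerance = 1e-6)

  comp <- collagen_composition()
  expect_equal(net_charge(comp, 20)$n_net, -(90 + 150 + 3),
               tolerance = 1e-4)
  de <- deamidate(comp, 0.24)
  expect_equal(net_charge(de, 20)$n_net, -(101 + 168 + 3),
               tolerance = 1e-4)
  # zero at the isoelectric point by definition of the root
  iep <- find_iep(de)
  expect_lt(abs(net_charge(de, iep)$n_net), 1e-2)
})

test_that("titration curve is strictly decreasing with a single zero crossing", {
  de <- deamidate(collagen_composition(), 0.24)
  grid <- seq(2, 12, by = 0.05)
  curve <- titration_curve(de, grid)
  expect_equal(nrow(curve), length(grid))
  expect_true(all(diff(curve$n_net) < 0))
  expect_equal(sum(diff(sign(curve$n_net)) != 0), 1)
  # positive plateau at low pH, zero crossing near 5.5
  expect_gt(curve$n_net[1], 200)
  expect_lt(abs(grid[which.min(abs(curve$n_net))] - 5.5), 0.2)
  # consistency with a scalar evaluation
  expect_equal(curve$n_net[grid == 7.4],
               net_charge(de, 7.4)$n_net, tolerance = 1e-12)
  expect_error(titration_curve(de, c(3, 2, 4)), "increasing")
})

test_that("printed charge anchors reproduce under the operating conditions", {
  de <- deamidate(collagen_composition(), 0.24)
  cs <- net_charge(de, 7.40, 37, 0.180)
  expect_lt(cs$n_net, 0)                       # net negative at pH 7.4
  expect_equal(abs(cs$n_net), 17.6, tolerance = 0.3 / 17.6)
  expect_equal(find_iep(de), 5.5, tolerance = 0.1 / 5.5)
  expect_gt(find_iep(collagen_composition()), 8.0)
})

test_that("IEP is scale-invariant, symmetric for balanced pairs, and needs a sign change", {
  de <- deamidate(collagen_composition(), 0.24)
  scaled <- de
  scaled$groups$count <- scaled$groups$count * 3L
  expect_equal(find_iep(scaled), find_iep(de), tolerance = 1e-3)

  sym <- ionizable_composition(rbind(
    ionizable_group("acid", 7L, 4.0, -1, 0),
    ionizable_group("base", 7L, 10.0, +1, 0)))
  pk <- correct_pka(sym$groups, 37, 0.18)
  expect_equal(find_iep(sym), mean(pk), tolerance = 1e-3)

  all_basic <- ionizable_composition(
    ionizable_group("base", 5L, 10.0, +1, 0))
  expect_error(find_iep(all_basic), "sign")
})

test_that("fixed-charge concentration is multilinear and matches the tabulated cells", {
  expect_equal(fixed_charge_concentration(0.136)$c_p * 1e8, 953,
               tolerance = 0.002)
  expect_equal(fixed_charge_concentration(0.227)$c_p * 1e8, 1591,
               tolerance = 0.002)
  base <- fixed_charge_concentration(0.1, 1.2, 3e5, 17.6)$c_p
  set.seed(7)
  for (s in runif(5, 0.5, 2)) {
    expect_equal(fixed_charge_concentration(0.1 * s, 1.2, 3e5, 17.6)$c_p,
                 base * s, tolerance = 1e-12)
    expect_equal(fixed_charge_concentration(0.1, 1.2 * s, 3e5, 17.6)$c_p,
                 base * s, tolerance = 1e-12)
    expect_equal(fixed_charge_concentration(0.1, 1.2, 3e5 * s, 17.6)$c_p,
                 base / s, tolerance = 1e-12)
    expect_equal(fixed_charge_concentration(0.1, 1.2, 3e5, 17.6 * s)$c_p,
                 base * s, tolerance = 1e-12)
  }
  expect_lt(fixed_charge_concentration(1e-9)$c_p, 1e-12)
  expect_error(fixed_charge_concentration(0), "0, 1")
  expect_error(fixed_charge_concentration(1.2), "0, 1")
})

test_that("packaged composition fixture mirrors the in-code default", {
  fx <- read_composition()
  expect_equal(fx$groups, collagen_composition()$groups)
  expect_equal(fx$asn_count, 46L)
  expect_equal(fx$gln_count, 75L)
})
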