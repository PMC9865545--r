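# two-wavelength Beer-Lambert quantification

test_that("forward readings are additive, linear, and ratio-invariant", {
  eps <- extinction_set()
  r0 <- predict_reading(0, 0, eps)
  expect_equal(c(r0$a325, r0$a260), c(0, 0))

  set.seed(5)
  for (i in 1:10) {
    c1 <- runif(2, 0, 0.1); c2 <- runif(2, 0, 0.1)
    ra <- predict_reading(c1[1], c1[2], eps)
    rb <- predict_reading(c2[1], c2[2], eps)
    rab <- predict_reading(c1[1] + c2[1], c1[2] + c2[2], eps)
    expect_equal(rab$a325, ra$a325 + rb$a325, tolerance = 1e-12)
    expect_equal(rab$a260, ra$a260 + rb$a260, tolerance = 1e-12)
    r2x <- predict_reading(2 * c1[1], 2 * c1[2], eps)
    expect_equal(r2x$a325, 2 * ra$a325, tolerance = 1e-12)
  }
  # pure-TA ratio independent of concentration
  pure <- vapply(c(0.01, 0.05, 0.2),
                 function(cc) { r <- predict_reading(cc, 0, eps)
                                r$a325 / r$a260 }, numeric(1))
  expect_equal(max(pure) - min(pure), 0, tolerance = 1e-12)
  expect_error(predict_reading(-1, 0, eps), ">= 0")
})

test_that("ratio matrix depends on composition ratio only and is monotone in TA", {
  eps <- extinction_set()
  grid <- geometric_grid(0.01, 1, 12)
  m <- build_ratio_matrix(grid, grid, eps)
  set.seed(6)
  for (s in runif(3, 0.2, 5)) {
    ms <- build_ratio_matrix(grid * s, grid * s, eps)
    expect_equal(ms$expected_ratio, m$expected_ratio,
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
  # along increasing TA at fixed CHDG the corrected ratio rises toward
  # the pure-TA signature
  for (j in seq_along(grid))
    expect_true(all(diff(m$expected_ratio[, j]) > 0))
  expect_error(build_ratio_matrix(c(2, 1), grid), "increasing")
  expect_error(build_ratio_matrix(numeric(0), grid), "non-empty")
})

test_that("composition matching equals exhaustive search and survives noise", {
  eps <- extinction_set()
  m <- build_ratio_matrix(geometric_grid(0.005, 0.5, 25),
                          geometric_grid(0.005, 0.5, 25), eps)
  # on-grid round trip
  r <- predict_reading(m$ta_grid[7], m$chdg_grid[19], eps)
  hit <- match_composition(r, m)
  expect_equal(hit$ta_over_chdg, m$ta_grid[7] / m$chdg_grid[19],
               tolerance = 1e-12)

  # off-grid reading: brute-force minimization over every cell
  obs_ratio <- function(r) (r$a325 / eps$eps_ta_325) /
    (r$a260 / eps$eps_chdg_260)
  set.seed(17)
  for (i in 1:10) {
    r <- predict_reading(runif(1, 0.005, 0.5), runif(1, 0.005, 0.5), eps)
    hit <- match_composition(r, m)
    brute <- which.min(abs(m$expected_ratio - obs_ratio(r)))
    expect_equal(abs(m$expected_ratio[hit$i, hit$j] - obs_ratio(r)),
                 abs(m$expected_ratio[brute] - obs_ratio(r)),
                 tolerance = 1e-12)
  }

  # 1% absorbance noise: matched composition ratio stays within one
  # geometric grid step of the truth in at least 95% of trials
  step <- m$ta_grid[2] / m$ta_grid[1]
  set.seed(23)
  ok <- 0L
  for (i in 1:100) {
    true_ratio <- m$ta_grid[13] / m$chdg_grid[10]
    r0 <- predict_reading(m$ta_grid[13], m$chdg_grid[10], eps)
    r <- spectrum_reading(r0$a325 * rnorm(1, 1, 0.01),
                          r0$a260 * rnorm(1, 1, 0.01))
    hit <- match_composition(r, m)
    if (abs(log(hit$ta_over_chdg / true_ratio)) <= 1.5 * log(step))
      ok <- ok + 1L
  }
  expect_gte(ok, 95L)

  expect_error(match_composition(spectrum_reading(0.5, 0), m), "A260")
})

test_that("calibration lines and two-wavelength inversion quantify an unknown", {
  eps <- extinction_set()
  ratio <- 2.5                                  # CHDG per TA, fixed
  c_ta <- seq(0.01, 0.06, by = 0.01)
  std_read <- predict_reading(c_ta, ratio * c_ta, eps)
  standards <- data.frame(c_ta = c_ta, c_chdg = ratio * c_ta,
                          a325 = std_read$a325, a260 = std_read$a260)
  unknown_conc <- c(0.037, ratio * 0.037)
  unk <- predict_reading(unknown_conc[1], unknown_conc[2], eps)

  cal <- calibrate_and_quantify(standards, unk)
  expect_equal(cal$lines$intercept, c(0, 0), tolerance = 1e-10)
  expect_equal(cal$lines$slope,
               c(eps$eps_ta_325 + ratio * eps$eps_chdg_325,
                 eps$eps_ta_260 + ratio * eps$eps_chdg_260),
               tolerance = 1e-10)
  expect_equal(cal$c_ta, unknown_conc[1], tolerance = 1e-10)
  expect_equal(cal$c_chdg, unknown_conc[2], tolerance = 1e-10)
  expect_lt(cal$consistency, 1e-10)

  # independent route: direct inversion of the extinction system
  direct <- solve_concentrations(unk, eps)
  expect_equal(c(direct$c_ta, direct$c_chdg), unknown_conc,
               tolerance = 1e-10)
  E <- matrix(c(eps$eps_ta_325, eps$eps_chdg_325,
                eps$eps_ta_260, eps$eps_chdg_260), 2, byrow = TRUE)
  expect_equal(unname(solve(E, c(unk$a325, unk$a260))), unknown_conc,
               tolerance = 1e-10)

  # 10% absorbance noise: recovered concentrations stay within 10% RSD
  set.seed(31)
  rec <- replicate(100, {
    noisy <- spectrum_reading(unk$a325 * rnorm(1, 1, 0.10),
                              unk$a260 * rnorm(1, 1, 0.10))
    calibrate_and_quantify(standards, noisy)$c_ta
  })
  expect_lt(sd(rec) / mean(rec), 0.10)

  expect_error(calibrate_and_quantify(standards[1:2, ], unk), "3 dilution")
  bad <- standards; bad$c_chdg[2] <- bad$c_chdg[2] * 2
  expect_error(calibrate_and_quantify(bad, unk), "fixed")
})

test_that("fraction released converts concentrations with clipping and unit handling", {
  expect_equal(fraction_released(0, loaded_mass = 55), 0)
  # full 55 mg load dissolved in 1 L -> 0.055 mg/mL -> fraction 1
  expect_equal(fraction_released(0.055, loaded_mass = 55), 1)
  expect_equal(fraction_released(0.0275, loaded_mass = 55), 0.5)
  expect_warning(out <- fraction_released(0.08, loaded_mass = 55),
                 "exceeds 1")
  expect_equal(out, 1)
  # molar input: c mol/L * M g/mol = g/L = mg/mL
  expect_equal(fraction_released(1e-5, loaded_mass = 17,
                                 molar_mass = 1500),
               1e-5 * 1500 * 1000 / 17, tolerance = 1e-12)
  expect_error(fraction_released(0.01, loaded_mass = 0), "loaded_mass")
})

test_that("negative absorbances are clipped and flagged", {
  expect_warning(r <- spectrum_reading(c(-0.01, 0.2), c(0.3, 0.4)),
                 "clipped")
  expect_equal(r$a325, c(0, 0.2))
  expect_equal(attr(r, "clipped"), c(TRUE, FALSE))
})
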