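test_that("extinction lookup is deterministic and ordered around the isosbestic point", {
  e690 <- lookup_extinction(690)
  expect_gt(e690$epsD, e690$epsO)      # deoxy dominates below ~800 nm
  e830 <- lookup_extinction(830)
  expect_gt(e830$epsO, e830$epsD)
  expect_identical(lookup_extinction(760), lookup_extinction(760))
  expect_error(lookup_extinction(600), "range")
  expect_error(lookup_extinction(1100), "range")
})

test_that("baseline tissue compositions reproduce the tabulated absorption values", {
  # muscle at 690 nm with 80% water, to four decimals
  muscle <- tissue_composition(75, 25, 0.80)
  expect_equal(round(mua_from_composition(muscle, 690), 4), 0.0170)
  # adipose and bone at 830 nm
  shallow <- tissue_composition(37.5, 12.5, 0.20)
  expect_equal(round(mua_from_composition(shallow, 830), 4), 0.0110)
  bone <- tissue_composition(37.5, 12.5, 0.32)
  expect_equal(round(mua_from_composition(bone, 830), 4), 0.0114)
  # hemoglobin-only branch
  expect_equal(round(mua_from_composition(muscle, 690,
                                          include_water = FALSE), 4), 0.0166)
  expect_equal(round(mua_from_composition(muscle, 830,
                                          include_water = FALSE), 4), 0.0208)
  # empty medium
  empty <- tissue_composition(0, 0, 0)
  expect_equal(mua_from_composition(empty, 760), 0)
  expect_error(tissue_composition(-1, 5), "non-negative")
})

test_that("absorption is linear in chromophore content", {
  set.seed(11)
  for (i in 1:20) {
    O <- runif(1, 0, 100); D <- runif(1, 0, 50); w <- runif(1)
    a <- runif(1, 0.1, 3)
    m1 <- mua_from_composition(tissue_composition(O, D, 0), 720,
                               include_water = FALSE)
    m2 <- mua_from_composition(tissue_composition(a * O, a * D, 0), 720,
                               include_water = FALSE)
    expect_equal(m2, a * m1, tolerance = 1e-12)
    mw <- mua_from_composition(tissue_composition(O, D, w), 720)
    expect_equal(mw, m1 + w * lookup_extinction(720)$muaWater,
                 tolerance = 1e-12)
  }
})

test_that("two-wavelength inversion coefficients satisfy their algebraic identities", {
  pair <- c(690, 830)
  co <- inversion_coefficients(pair)
  # frozen expected values from the direct 2x2 inversion of the packaged table
  e1 <- lookup_extinction(690); e2 <- lookup_extinction(830)
  kd <- log(10) * 1e-7 * (e1$epsO * e2$epsD - e2$epsO * e1$epsD)
  expect_equal(co$aMinus, (e2$epsD - e2$epsO) / kd, tolerance = 1e-14)
  expect_equal(co$bMinus, (e1$epsO - e1$epsD) / kd, tolerance = 1e-14)

  set.seed(7)
  M <- log(10) * 1e-7 *
    matrix(c(e1$epsO, e2$epsO, e1$epsD, e2$epsD), 2, 2)
  for (i in 1:1000) {
    dmua <- rnorm(2, 0, 1e-3)
    hb <- solve(M, dmua)
    expect_equal(co$aMinus * dmua[1] + co$bMinus * dmua[2], sum(hb),
                 tolerance = 1e-10)
    expect_equal(co$aPlus * dmua[1] + co$bPlus * dmua[2], hb[2] - hb[1],
                 tolerance = 1e-10)
  }
  expect_error(inversion_coefficients(c(690, 690)), "degenerate")
})

test_that("hemoglobin changes round-trip through absorption changes", {
  pair <- c(690, 830)
  e <- lapply(pair, lookup_extinction)
  k <- log(10) * 1e-7
  dmua <- vapply(e, function(x) k * (x$epsO * 5 + x$epsD * (-2)), numeric(1))
  hb <- delta_hb_from_delta_mua(dmua[1], dmua[2], pair)
  expect_equal(hb$dO, 5, tolerance = 1e-12)
  expect_equal(hb$dD, -2, tolerance = 1e-12)
  expect_equal(hb$dT, 3, tolerance = 1e-12)
  z <- delta_hb_from_delta_mua(0, 0, pair)
  expect_identical(unname(unlist(z)), c(0, 0, 0))

  # full composition round trip with known water subtracted
  comp <- tissue_composition(60, 20, 0.5)
  mua <- vapply(pair, function(l) mua_from_composition(comp, l), numeric(1))
  water <- vapply(pair, function(l) 0.5 * lookup_extinction(l)$muaWater,
                  numeric(1))
  hb2 <- delta_hb_from_delta_mua(mua[1] - water[1], mua[2] - water[2], pair)
  expect_equal(hb2$dO, 60, tolerance = 1e-9)
  expect_equal(hb2$dD, 20, tolerance = 1e-9)
})

test_that("scattering power law matches the tabulated 830 nm values", {
  expect_equal(round(mus_prime_power_law(1.0, 0.1, 830), 2), 0.98)
  expect_equal(round(mus_prime_power_law(0.5, 1, 830), 2), 0.42)
  expect_equal(signif(mus_prime_power_law(1.5, 0.7, 830), 2), 1.3)
  expect_equal(mus_prime_power_law(1.2, 0, 901), 1.2)  # b = 0: flat
  expect_error(mus_prime_power_law(-1, 0.5, 830), "positive")
  expect_error(mus_prime_power_law(1, 0.5, -830), "positive")
})

test_that("blood unit conversions reproduce the printed working values", {
  expect_equal(signif(blood_concentration(15) / 1000, 2), 2.3)  # mM
  expect_equal(blood_concentration(0), 0)
  expect_equal(round(100 * blood_volume_fraction(100, 2300), 1), 4.3)
  expect_equal(round(100 * blood_volume_fraction(50, 2300), 1), 2.2)
  expect_error(blood_volume_fraction(100, 0), "non-zero")
})
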