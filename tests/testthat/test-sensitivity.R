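test_that("partial pathlengths obey the chain rule and match a Richardson oracle", {
  media <- fixture_two_layer_pair()
  med <- media[[1]]
  L <- pathlength_matrix(med)
  # sum over layers vs a global absorption derivative
  for (kind in c("SDI25", "SDPhi37", "DSI")) {
    glob <- oracle_richardson(function(mua_shift)
      fdnirs:::model_datavalue(perturb_mua(med, rep(mua_shift, 2)), kind),
      0, 1e-5)
    expect_lt(abs(sum(L[, kind]) / glob - 1), 1e-3)
  }
  # per-layer values vs higher-order differentiation
  for (kind in c("SDI25", "DSPhi")) {
    rich <- oracle_richardson(function(d)
      fdnirs:::model_datavalue(perturb_mua(med, c(d, 0)), kind), 0, 2e-5)
    expect_lt(abs(L[1, kind] / rich - 1), 1e-4)
  }
  # single-layer medium: the only layer carries the whole derivative
  p <- fdnirs:::tissue_layer_properties(2, 690)
  one <- layered_medium(list(optical_layer(p$mua, p$musp, Inf)))
  pl <- partial_pathlengths(one, "SDI25")
  expect_equal(pl$lk[1], pl$total)
  # intensity pathlengths are negative (more absorption, less light); the
  # totals dominate over any small opposite-signed layer contribution
  expect_true(all(L[, c("SDI25", "SDI37")] < 0))
  expect_true(all(colSums(L[, c("SDI25", "SDI37"), drop = FALSE]) < 0))
})

test_that("normalized sensitivities sum to one and order by depth reach", {
  media <- fixture_two_layer_pair()   # L1 = 7 mm
  for (med in media) {
    S <- sensitivity_matrix(med)
    expect_equal(unname(colSums(S)), rep(1, 6), tolerance = 1e-12)
  }
  S2 <- sensitivity_matrix(media[[1]])[2, ]
  # deeper-layer sensitivity grows along SD25 -> SD37 -> DS, phase > intensity
  expect_lt(S2["SDI25"], S2["SDI37"])
  expect_lt(S2["SDI37"], S2["DSI"])
  expect_gt(S2["SDPhi25"], S2["SDI25"])
  expect_gt(S2["SDPhi37"], S2["SDI37"])
  expect_gt(S2["DSPhi"], S2["DSI"])
  # a very deep interface is invisible to the short channel
  deep <- make_subject(30, Inf)
  expect_lt(sensitivity_matrix(deep)[2, "SDI25"], 0.05)
})

test_that("scenarios map to absorption changes with the right spectra", {
  pair <- c(690, 830)
  zero <- hemodynamic_scenario("venous", dT = c(0, 0, 0))
  expect_true(all(scenario_to_absorption(zero, pair) == 0))
  art <- hemodynamic_scenario("arterial", dD = c(0, 20, 0))
  ch <- scenario_to_absorption(art, pair)
  expect_gt(ch[2, 1], 0)   # desaturation raises absorption at 690
  expect_lt(ch[2, 2], 0)   # and lowers it at 830
  expect_true(all(ch[c(1, 3), ] == 0))
  ven <- hemodynamic_scenario("venous", dT = c(5, 10, 0), saturation = 0.75)
  chv <- scenario_to_absorption(ven, pair)
  for (i in 1:2) {
    e <- lookup_extinction(pair[i])
    hand <- log(10) * 1e-7 * (e$epsO * 0.75 + e$epsD * 0.25) * c(5, 10, 0)
    expect_equal(unname(chv[, i]), hand, tolerance = 1e-12)
  }
  expect_error(hemodynamic_scenario("venous", dT = c(5, 10), saturation = 2),
               "saturation")
  expect_error(hemodynamic_scenario("arterial", dD = c(-1, 2)),
               "non-negative")
})

test_that("the ratio engine agrees with the brute-force inversion oracle", {
  pair <- c(690, 830)
  media <- fixture_three_layer_pair()
  sens <- lapply(media, sensitivity_matrix)
  # uniform absorption change at both wavelengths: every ratio is 1
  uni <- matrix(1e-4, 3, 2)
  expect_equal(ratio_deltaT("DSI", "SDPhi25", media, uni, pair, sens = sens),
               1, tolerance = 1e-10)
  set.seed(5)
  for (i in 1:40) {
    change <- matrix(rnorm(6, 0, 2e-4), 3, 2)
    kp <- sample(data_type_kinds(), 2)
    expect_equal(ratio_deltaT(kp[1], kp[2], media, change, pair, sens = sens),
                 oracle_ratio(kp[1], kp[2], sens, change, pair, "dT"),
                 tolerance = 1e-10)
    expect_equal(ratio_deoxy_oxy(kp[1], kp[2], media, change, pair,
                                 sens = sens),
                 oracle_ratio(kp[1], kp[2], sens, change, pair, "dDmdO"),
                 tolerance = 1e-10)
  }
})

test_that("bone-inert scenarios depress the long-over-short intensity ratio at shallow bone", {
  pair <- c(690, 830)
  media <- make_subject_pair(1.5, 13.5)   # thin adipose, bone depth 15 mm
  sens <- lapply(media, sensitivity_matrix)
  ven <- scenario_to_absorption(
    hemodynamic_scenario("venous", dT = c(5, 10, 0)), pair)
  expect_lt(ratio_deltaT("SDI37", "SDI25", media, ven, pair, sens = sens), 1)
  art <- scenario_to_absorption(
    hemodynamic_scenario("arterial", dD = c(5, 10, 0)), pair)
  # phase-based ratio does not exceed the intensity-based ratio
  ri <- ratio_deoxy_oxy("SDI37", "SDI25", media, art, pair, sens = sens)
  rp <- ratio_deoxy_oxy("SDPhi37", "SDPhi25", media, art, pair, sens = sens)
  expect_lte(rp, ri)
})

test_that("small perturbations recover as sensitivity-weighted effective changes", {
  media <- fixture_two_layer_pair()
  med <- media[[1]]
  S <- sensitivity_matrix(med)
  L <- pathlength_matrix(med)
  dmua <- c(4e-4, 8e-4)
  for (kind in c("SDI25", "SDPhi37")) {
    y0 <- fdnirs:::model_datavalue(med, kind)
    y1 <- fdnirs:::model_datavalue(perturb_mua(med, dmua), kind)
    eff <- (y1 - y0) / sum(L[, kind])
    expect_lt(abs(eff / sum(S[, kind] * dmua) - 1), 0.03)
  }
})
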