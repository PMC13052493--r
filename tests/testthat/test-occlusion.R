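test_that("protocol defaults match the venous and arterial designs", {
  v <- occlusion_protocol("venous")
  expect_equal(c(v$baseline_s, v$occlusion_s, v$recovery_s), c(60, 60, 60))
  expect_equal(v$window_s, 10)
  expect_equal(v$cuff_mmHg, 60)
  a <- occlusion_protocol("arterial")
  expect_equal(c(a$baseline_s, a$occlusion_s, a$recovery_s), c(120, 120, 120))
  expect_equal(a$window_s, 60)
  expect_equal(a$cuff_mmHg, 200)
  expect_error(occlusion_protocol("venous", window_s = 100), "window")
})

test_that("modified Beer-Lambert conversion has the right null, sign and scale", {
  prot <- occlusion_protocol("venous")
  time_s <- seq(0, 180, 1 / 2.4)
  baseline <- list(mua = 0.017, musp = 0.5)
  Y <- rep(-3.5, length(time_s))
  expect_true(all(mbll_delta_mua(Y, time_s, baseline, "SDI25", prot) == 0))
  # an intensity drop maps to a positive absorption change
  L <- homogeneous_pathlength(0.017, 0.5, "SDI25")
  expect_lt(L, 0)
  Y2 <- Y - 0.01 * (time_s > 60)
  dmua <- mbll_delta_mua(Y2, time_s, baseline, "SDI25", prot)
  expect_gt(dmua[length(dmua)], 0)
  # a known homogeneous absorption step round-trips within linearization error
  step <- 5e-4
  for (kind in c("SDI25", "SDPhi37", "DSI")) {
    y0 <- fdnirs:::model_datavalue(
      layered_medium(list(optical_layer(0.017, 0.5, Inf))), kind)
    y1 <- fdnirs:::model_datavalue(
      layered_medium(list(optical_layer(0.017 + step, 0.5, Inf))), kind)
    Ys <- c(rep(y0, 150), rep(y1, 283))
    rec <- mbll_delta_mua(Ys, time_s, baseline, kind, prot)
    expect_lt(abs(rec[length(rec)] / step - 1), 0.02)
  }
})

test_that("hemoglobin traces invert programmed concentration changes", {
  pair <- c(690, 830)
  z <- traces_to_hemoglobin(numeric(5), numeric(5), 1:5, pair)
  expect_true(all(z$dT_uM == 0))
  e <- lapply(pair, lookup_extinction)
  k <- log(10) * 1e-7
  t_s <- seq(0, 10, 0.5)
  dO <- 0.5 * t_s; dD <- -0.2 * t_s
  d1 <- k * (e[[1]]$epsO * dO + e[[1]]$epsD * dD)
  d2 <- k * (e[[2]]$epsO * dO + e[[2]]$epsD * dD)
  tr <- traces_to_hemoglobin(d1, d2, t_s, pair)
  expect_equal(tr$dO_uM, dO, tolerance = 1e-10)
  expect_equal(tr$dD_uM, dD, tolerance = 1e-10)
  expect_error(traces_to_hemoglobin(d1, d2[-1], t_s, pair), "misaligned")
})

test_that("blood flow converts an initial hemoglobin slope into perfusion units", {
  prot <- occlusion_protocol("venous")
  t_s <- seq(0, 180, 1 / 2.4)
  ramp <- pmax(pmin(t_s - 60, 60), 0)   # 1 uM/s during occlusion
  tr <- structure(data.frame(time_s = t_s, dO_uM = 0.75 * ramp,
                             dD_uM = 0.25 * ramp, dT_uM = ramp),
                  class = c("hemodynamic_trace", "data.frame"))
  bf <- blood_flow(tr, prot, ctHb = 2300)
  expect_equal(bf$rate, 6000 / 2300, tolerance = 1e-9)  # 2.61 mL/100mL/min
  expect_equal(bf$se, 0, tolerance = 1e-9)
  flat <- tr; flat$dT_uM <- 0 * flat$dT_uM
  expect_equal(blood_flow(flat, prot)$rate, 0, tolerance = 1e-12)
  short <- tr[tr$time_s < 65, ]
  expect_error(blood_flow(short, prot), "window")
  expect_error(blood_flow(tr, occlusion_protocol("arterial")), "venous")
})

test_that("oxygen consumption converts a desaturation slope into metabolic units", {
  prot <- occlusion_protocol("arterial")
  t_s <- seq(0, 360, 1 / 2.4)
  ramp <- pmax(pmin(t_s - 120, 120), 0)
  tr <- structure(data.frame(time_s = t_s, dO_uM = -0.1 * ramp,
                             dD_uM = 0.1 * ramp,
                             dT_uM = 0 * ramp),
                  class = c("hemodynamic_trace", "data.frame"))
  oc <- oxygen_consumption(tr, prot)
  expect_equal(oc$rate, 2.4, tolerance = 1e-9)  # 4 x 0.1 uM/s x 6
  zero <- tr; zero$dO_uM <- zero$dD_uM <- 0 * t_s
  expect_equal(oxygen_consumption(zero, prot)$rate, 0, tolerance = 1e-12)
  expect_error(oxygen_consumption(tr, occlusion_protocol("venous")),
               "arterial")
})

test_that("rate ratios tabulate cleanly, flagging zero denominators", {
  rates <- data.frame(kind = data_type_kinds(), quantity = "BF",
                      rate = rep(1.5, 6), se = 0.1, slope_uM_s = 0.01)
  rep1 <- ratio_report(rates)
  expect_true(all(rep1$ratio == 1))
  rates$rate[rates$kind == "SDI25"] <- 0
  rep2 <- ratio_report(rates)
  expect_true(is.na(rep2$ratio[rep2$kind_pair == "SDI37/SDI25"]))
  expect_error(ratio_report(rates[-1, ]), "missing kind")
})

test_that("arterial pure desaturation leaves total hemoglobin flat end-to-end", {
  media <- fixture_muscle_homogeneous_pair()
  sc <- hemodynamic_scenario("arterial", dD = 12)
  prot <- occlusion_protocol("arterial")
  quiet <- instrument_model(amp_noise_rel = 0, phase_noise_rad = 0)
  sim <- simulate_occlusion(media, sc, prot, quiet, seed = 3)
  res <- analyze_occlusion(sim, prot, kinds = c("SDI25", "SDPhi25"))
  for (kind in c("SDI25", "SDPhi25")) {
    tr <- res$traces[[kind]]
    sel <- tr$time_s >= 120 & tr$time_s <= 180
    dT_slope <- coef(lm(tr$dT_uM[sel] ~ tr$time_s[sel]))[2]
    dD_slope <- coef(lm(tr$dD_uM[sel] ~ tr$time_s[sel]))[2]
    expect_lt(abs(dT_slope), 0.05 * abs(dD_slope))
  }
})
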