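test_that("Lloyd-Taylor response has its reference identity and shape", {
  expect_equal(reco_model(10, rref = 3.2, e0 = 308.56), 3.2)
  expect_equal(reco_model(20, rref = 2, e0 = 308.56), 4.606, tolerance = 1e-3)
  temps <- seq(-5, 35, by = 0.5)
  expect_true(all(diff(reco_model(temps, 2, 200)) > 0))
  expect_error(reco_model(-60, 2, 200), "T0")
})

test_that("Michaelis-Menten light response hits its limits", {
  expect_identical(light_response(0, 0.05, 30), 0)
  expect_equal(light_response(1e9, 0.05, 30), 30, tolerance = 1e-6)
  # half-saturation identity: PAR = gpmax / alpha gives gpmax / 2
  expect_equal(light_response(30 / 0.05, 0.05, 30), 15)
})

test_that("campaign fits recover noiseless parameters and fall back sanely", {
  t_c <- seq(5, 25, length.out = 10)
  reco <- reco_model(t_c, rref = 3, e0 = 200)
  fit <- fit_reco_campaign(reco, t_c)
  expect_false(fit$fallback)
  expect_equal(fit$rref, 3, tolerance = 1e-6)
  expect_equal(fit$e0, 200, tolerance = 1e-6)

  # no temperature spread: e0 fixed, rref from the closed form
  flat <- fit_reco_campaign(rep(reco_model(17, 2.5, 308.56), 6), rep(17, 6))
  expect_true(flat$fallback)
  expect_equal(flat$e0, 308.56)
  expect_equal(flat$rref, 2.5, tolerance = 1e-9)
  expect_error(fit_reco_campaign(c(1, 2, 3), c(5, 10, 15)), "fewer than 4")

  par <- c(50, 150, 300, 600, 1000, 1500)
  gep <- light_response(par, alpha = 0.05, gpmax = 30)
  lfit <- fit_light_campaign(gep, par)
  expect_equal(lfit$alpha, 0.05, tolerance = 1e-6)
  expect_equal(lfit$gpmax, 30, tolerance = 1e-6)
  expect_false(lfit$degenerate)

  dead <- fit_light_campaign(rep(0, 6), par)
  expect_true(dead$degenerate)
  expect_error(fit_light_campaign(gep, rep(500, 6)), "PAR span")
})

test_that("observed GEP is NEP plus modelled respiration", {
  expect_equal(gep_observed(5, 10, rref = 3, e0 = 308.56), 8)
  expect_equal(gep_observed(-2, 10, rref = 2, e0 = 308.56), 0)
  t_c <- c(8, 12, 19)
  expect_equal(gep_observed(c(1, 2, 3), t_c, 2.4, 250),
               c(1, 2, 3) + reco_model(t_c, 2.4, 250))
  expect_error(gep_observed(1, NA, 2, 300), "missing temperature")
})

test_that("parameter interpolation is exact at anchors and linear between", {
  camp <- data.frame(doy = c(100, 110), rref = c(2, 4), e0 = c(200, 300),
                     alpha = c(0.04, 0.06), gpmax = c(10, 30))
  at_anchor <- interpolate_params(camp, 100.5)
  expect_equal(at_anchor$rref, 2)
  expect_equal(at_anchor$gpmax, 10)
  mid <- interpolate_params(camp, 105.5)
  expect_equal(mid$rref, 3)
  expect_equal(mid$e0, 250)
  expect_equal(mid$alpha, 0.05)
  expect_equal(mid$gpmax, 20)
  # hold-constant extrapolation beyond the campaign span
  ends <- interpolate_params(camp, c(90, 120))
  expect_equal(ends$gpmax, c(10, 30))
  single <- interpolate_params(camp[1, ], c(90, 100, 120))
  expect_equal(single$rref, rep(2, 3))
  expect_error(interpolate_params(camp[0, ], 100), "no fittable")
})

test_that("30-min reconstruction conserves NEP = GEP - Reco", {
  drivers <- data.frame(time = 100 + seq(0, 23.5, 0.5) / 24,
                        par = c(rep(0, 12), seq(0, 1200, length.out = 24),
                                rep(0, 12)),
                        t_soil_c = 10 + 5 * sin(seq(0, 2 * pi, length.out = 48)))
  params <- data.frame(time = drivers$time, rref = 2, e0 = 300,
                       alpha = 0.05, gpmax = 25)
  out <- reconstruct_30min(params, drivers)
  expect_identical(out$nep, out$gep - out$reco)
  expect_true(all(out$gep[drivers$par == 0] == 0))
  night <- drivers$par == 0
  expect_equal(out$nep[night], -out$reco[night])
  expect_error(reconstruct_30min(params[-1, ], drivers), "grids")
})

test_that("solar day window behaves at the equinox and midsummer", {
  eq <- day_window(80, latitude = 52.43)
  expect_lt(abs(unname(diff(eq)) - 12), 0.25)
  june <- day_window(172, latitude = 52.43)
  expect_gt(unname(diff(june)), 16)
  expect_error(day_window(172, latitude = 70), "polar")
  # PAR-threshold mode recovers the generator's configured solar window
  cfg <- quiet_config()
  drv <- generate_drivers(cfg)
  pw <- day_window(150, cfg$latitude, mode = "par", drivers = drv)
  sw <- day_window(150, cfg$latitude)
  expect_lt(max(abs(pw - sw)), 0.5 + 1e-9)
})

test_that("daily GEP sum matches hand arithmetic and a brute-force oracle", {
  # constant 10 umol m-2 s-1 over 24 daylight half-hours
  series <- data.frame(time = 120 + seq(0, 23.5, 0.5) / 24,
                       gep = rep(10, 48))
  expect_equal(daily_gep(series, 120, c(6, 18)), 5.189, tolerance = 1e-3)
  expect_identical(daily_gep(data.frame(time = series$time, gep = 0),
                             120, c(6, 18)), 0)
  # brute force: explicit per-step summation over the same window
  set.seed(7)
  series$gep <- runif(48, 0, 25)
  h <- (series$time - 120) * 24 + 0.25
  brute <- sum(series$gep[h >= 6 & h < 18]) * 1800 * 12.011e-6
  expect_equal(daily_gep(series, 120, c(6, 18)), brute)
  # additivity over disjoint sub-windows
  expect_equal(daily_gep(series, 120, c(6, 12)) +
                 daily_gep(series, 120, c(12, 18)),
               daily_gep(series, 120, c(6, 18)))
  # a gap inside the window is an error
  gappy <- series[-30, ]
  expect_error(daily_gep(gappy, 120, c(6, 18)), "gaps")
})

test_that("daily PAR averages only the daylight window", {
  drv <- data.frame(time = 130 + seq(0, 23.5, 0.5) / 24,
                    par = rep(800, 48))
  expect_equal(daily_par(drv, 130, c(6, 18)), 800)
  # half-sinusoid peaking at 1000: daylight mean ~ 2000 / pi
  h <- seq(0, 23.5, 0.5)
  drv$par <- ifelse(h >= 6 & h < 18, 1000 * sin(pi * (h - 6) / 12), 0)
  expect_equal(daily_par(drv, 130, c(6, 18)), 2000 / pi, tolerance = 0.01)
  # nighttime values never enter the mean
  drv$par[h < 6 | h >= 18] <- 1e6
  expect_equal(daily_par(drv, 130, c(6, 18)), 2000 / pi, tolerance = 0.01)
})
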