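test_that("season configuration enforces its invariants", {
  expect_s3_class(season_config(), "season_config")
  expect_error(season_config(start_doy = 150, lai_peak_doy = 140))
  expect_error(season_config(start_doy = 200, end_doy = 150))
  expect_error(season_config(ndvi_soil = 0.95, ndvi_inf = 0.9))
  expect_error(season_config(conc_noise_ppm = -1))
  expect_error(season_config(lai_start = 5, lai_max = 4))
})

test_that("drivers are deterministic, diurnal and dark at night", {
  cfg <- quiet_config(seed = 5)
  drv <- generate_drivers(cfg)
  expect_identical(drv, generate_drivers(cfg))
  # 30-min regular grid
  expect_equal(unique(round(diff(drv$time), 10)), 1 / 48)
  # noiseless noon PAR equals the day's configured clear-sky amplitude
  noon <- drv[drv$hour == 12 & drv$doy == 150, ]
  expect_equal(noon$par, cropgep:::.noon_amplitude(150, cfg))
  # exactly zero outside the solar window, positive inside
  for (d in c(70, 120, 190)) {
    win <- day_window(d, cfg$latitude)
    day <- drv[drv$doy == d, ]
    expect_true(all(day$par[day$hour <= win[1] | day$hour >= win[2]] == 0))
    inside <- day$hour > win[1] + 0.5 & day$hour < win[2] - 0.5
    expect_true(all(day$par[inside] > 0))
  }
  # a different seed changes the weather but not the grid
  drv2 <- generate_drivers(season_config(seed = 99))
  expect_identical(drv2$time, drv$time)
  expect_false(identical(drv2$par, drv$par))
})

test_that("LAI phenology peaks at the configured maximum and senesces", {
  cfg <- season_config(lai_max = 4, lai_peak_doy = 148)
  lai <- generate_lai_curve(cfg)
  expect_equal(max(lai$lai), 4, tolerance = 0.01)
  expect_lte(abs(lai$doy[which.max(lai$lai)] - 148), 1)
  pre <- lai$lai[lai$doy <= 148]
  expect_true(all(diff(pre) >= 0))
  # green LAI tracks total LAI through green-up, then falls away faster
  expect_equal(lai$lai_green[lai$doy <= 148], pre)
  late <- lai[lai$doy == cfg$end_doy, ]
  expect_lt(late$lai_green, late$lai)
  # standing (partly dead) leaf area plateaus at 2-3 m2 m-2
  expect_gt(late$lai, 2)
  expect_lt(late$lai, 3)
  # with no green-fraction decline the two curves are identical
  lai0 <- generate_lai_curve(season_config(green_fraction_decline = 0))
  expect_identical(lai0$lai_green, lai0$lai)
})

test_that("reflectance saturates with green LAI as configured", {
  cfg <- quiet_config(ndvi_soil = 0.15, ndvi_inf = 0.9, k_ext = 0.8)
  bare <- generate_reflectance(0, cfg)
  expect_equal(ndvi(bare$rho850, bare$rho670), 0.15, tolerance = 1e-9)
  dense <- generate_reflectance(50, cfg)
  expect_equal(ndvi(dense$rho850, dense$rho670), 0.9, tolerance = 1e-6)
  # hand evaluation: 0.9 - 0.75 exp(-1.6)
  two <- generate_reflectance(2, cfg)
  expect_equal(ndvi(two$rho850, two$rho670), 0.7486, tolerance = 1e-4)
  expect_error(generate_reflectance(-1, cfg))
  # noisy reflectance stays physical and reproducible
  noisy_cfg <- season_config(refl_noise = 0.02, seed = 3)
  r1 <- generate_reflectance(c(0, 1, 2, 4), noisy_cfg)
  expect_identical(r1, generate_reflectance(c(0, 1, 2, 4), noisy_cfg))
  expect_true(all(r1 >= 0))
})

test_that("campaign closures honour the field protocol and the truth", {
  cfg <- quiet_config(seed = 11)
  truth <- generate_truth(cfg)
  for (d in campaign_days(cfg)) {
    n_pairs <- length(generate_closures(d, truth)) / 2
    expect_gte(n_pairs, 5)
    expect_lte(n_pairs, 12)
  }
  cl <- generate_closures(120, truth)
  expect_true(all(vapply(cl, function(x)
    length(x$t_s) %in% c(120L, 180L), TRUE)))
  # zero noise: Eq.-style flux recomputation returns the true flux
  tr <- attr(cl, "truth")
  fx <- do.call(rbind, lapply(cl, closure_flux))
  m <- merge(fx, tr, by = "closure_id")
  expect_lt(max(abs(m$flux - m$flux_true) /
                  pmax(abs(m$flux_true), 1e-9)), 1e-9)
  expect_error(generate_closures(400, truth), "does not cover")
  # determinism of the stochastic path
  ncfg <- season_config(seed = 8)
  ntruth <- generate_truth(ncfg)
  expect_identical(generate_closures(120, ntruth),
                   generate_closures(120, ntruth))
})

test_that("truth bundle satisfies the flux identities everywhere", {
  truth <- generate_truth(season_config(seed = 2))
  f <- truth$fluxes30
  expect_identical(f$nep, f$gep - f$reco)
  expect_true(all(f$gep[truth$drivers$par == 0] == 0))
  expect_true(all(f$reco > 0))
  expect_true(all(truth$params_true$gpmax > 0))
})

test_that("a full generated season is reproducible bit for bit", {
  cfg <- season_config(seed = 31)
  s1 <- generate_season(cfg, year = 2012L)
  s2 <- generate_season(cfg, year = 2012L)
  expect_identical(s1$daily, s2$daily)
  expect_identical(s1$closures, s2$closures)
  expect_identical(nrow(s1$daily), length(sampling_days(cfg)))
  expect_true(all(c("gep_d", "par_d", "lai", "ndvi", "savi", "swdrvi",
                    "pri") %in% names(s1$daily)))
})
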