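test_that("concentration slope fit matches exact lines and the OLS oracle", {
  tt <- 0:119
  cl <- chamber_closure("exact", t_s = tt, co2_ppm = 400 + 0.05 * tt,
                        t_air_c = 20)
  sl <- fit_concentration_slope(cl, trim_s = 0)
  expect_equal(sl$slope, 0.05, tolerance = 1e-12)
  expect_equal(sl$r2, 1, tolerance = 1e-12)

  # degenerate variance convention: flat trace gets slope 0, r2 0
  flat <- chamber_closure("flat", t_s = tt, co2_ppm = rep(400, 120),
                          t_air_c = 20)
  slf <- fit_concentration_slope(flat, trim_s = 0)
  expect_identical(slf$slope, 0)
  expect_identical(slf$r2, 0)

  # 120 noisy points against the textbook normal-equation oracle
  set.seed(42)
  co2 <- 400 + 0.03 * tt + rnorm(120, 0, 0.5)
  noisy <- chamber_closure("noisy", t_s = tt, co2_ppm = co2, t_air_c = 20)
  sln <- fit_concentration_slope(noisy, trim_s = 0)
  oracle <- ols_oracle(tt, co2)
  expect_equal(sln$slope, oracle$slope, tolerance = 1e-12)
  expect_equal(sln$r2, oracle$r2, tolerance = 1e-12)
})

test_that("closure validation rejects short and ill-ordered traces by name", {
  expect_error(chamber_closure("tiny", t_s = 0:5, co2_ppm = rep(400, 6),
                               t_air_c = 10),
               "tiny.*fewer than 10")
  expect_error(chamber_closure("bad", t_s = c(0:8, 8), co2_ppm = rep(400, 10),
                               t_air_c = 10),
               "strictly increasing")
  cl <- chamber_closure("trimmed", t_s = 0:14, co2_ppm = 400 + 0:14,
                        t_air_c = 10)
  expect_error(fit_concentration_slope(cl, trim_s = 10), "after trimming")
})

test_that("molar volume follows the ideal gas law", {
  expect_equal(molar_volume(0, 101325), 0.022414, tolerance = 1e-4)
  expect_equal(molar_volume(25, 101325), 0.024466, tolerance = 1e-4)
  expect_equal(molar_volume(25, 2 * 101325), molar_volume(25, 101325) / 2)
  expect_error(molar_volume(25, 0), "pressure")
})

test_that("flux equation scales correctly and matches hand arithmetic", {
  mv <- molar_volume(25, 101325)
  expect_identical(compute_flux(0, mv = mv), 0)
  # unit slope with the default chamber (0.296 m3 over a 0.75 x 0.75 m collar)
  expect_equal(compute_flux(1, 0.296, 0.5625, mv), 21.51, tolerance = 1e-3)
  expect_equal(compute_flux(1, 2 * 0.296, 0.5625, mv),
               2 * compute_flux(1, 0.296, 0.5625, mv))
  expect_equal(compute_flux(3.7, 0.296, 0.5625, mv),
               3.7 * compute_flux(1, 0.296, 0.5625, mv))
  expect_error(compute_flux(1, -1, 0.5625, mv), "positive")
})

test_that("chamber kind sets the ecological sign convention", {
  tt <- 0:119
  # concentration drawn down in a transparent chamber = canopy uptake
  down <- chamber_closure("uptake", chamber_kind = "transparent",
                          t_s = tt, co2_ppm = 420 - 0.1 * tt, t_air_c = 20)
  rec <- closure_flux(down)
  expect_identical(rec$flux_kind, "NEP")
  expect_gt(rec$flux, 0)
  expect_lt(rec$raw_slope, 0)
  # concentration rising in an opaque chamber = respiration release
  up <- chamber_closure("resp", chamber_kind = "opaque",
                        t_s = 0:179, co2_ppm = 400 + 0.05 * (0:179),
                        t_air_c = 20)
  rec2 <- closure_flux(up)
  expect_identical(rec2$flux_kind, "Reco")
  expect_gt(rec2$flux, 0)
})

test_that("QC keeps good fits, drops bad large fluxes, reviews near-zero ones", {
  recs <- data.frame(flux = c(10, 12, 0.05, -0.3, 8),
                     r2 = c(0.85, 0.5, 0.3, 0.79, 0.801))
  out <- qc_filter(recs, r2_min = 0.8, near_zero_abs = 0.5)
  expect_identical(out$qc_flag,
                   c("pass", "excluded_r2", "near_zero_review",
                     "near_zero_review", "pass"))
  expect_identical(out$qc_pass, c(TRUE, FALSE, TRUE, TRUE, TRUE))
  strict <- qc_filter(recs, keep_near_zero = FALSE)
  expect_identical(strict$qc_pass, c(TRUE, FALSE, FALSE, FALSE, TRUE))
})
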