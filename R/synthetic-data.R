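# Synthetic crop-season generator with known ground truth.
#
# Emulates a mid-latitude cropland field experiment: continuous 30-min
# PAR/temperature drivers, a double-logistic LAI phenology with a
# post-peak green-fraction decline, campaign-style chamber closures with
# linear concentration drift plus noise, and 4-band canopy reflectance
# that saturates with green LAI (so NDVI flattens early in dense winter
# crops, reproducing the vegetative/reproductive hysteresis of the
# GEP-NDVI relation).

#' Run code with a temporary RNG seed, restoring the caller's RNG state
#' @noRd
.with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Configuration of one synthetic crop season
#'
#' Defaults describe a winter cereal at a temperate lowland site
#' (52.43 N): season from early March to early August, LAI peaking in
#' late May, photosynthetic capacity tied to green LAI, and clear-sky
#' noon PAR around 1600 umol m-2 s-1 in midsummer (daylight-mean PAR_d
#' of roughly 600-700 umol m-2 s-1, peaking above 1000).
#'
#' @param crop_label Crop name carried through output tables.
#' @param start_doy,end_doy Season limits, day of year.
#' @param lai_max Seasonal maximum LAI, m2 m-2.
#' @param lai_start LAI already present at the season start, m2 m-2
#'   (overwintered canopy; winter cereals resume growth in spring with a
#'   dense green stand, spring crops start from 0).
#' @param lai_peak_doy Day of year of the LAI maximum.
#' @param lai_rise_rate,lai_fall_rate Logistic rates of green-up and
#'   senescence, d-1.
#' @param lai_plateau Post-peak total-LAI plateau, m2 m-2 (standing dead
#'   plus remaining green leaves; total LAI declines to this level while
#'   green LAI keeps falling).
#' @param green_fraction_decline Linear decline rate of the green
#'   fraction after the LAI peak, d-1 (0 keeps green LAI = LAI).
#' @param gpmax_per_lai Asymptotic GEP per unit green LAI,
#'   umol CO2 m-2 s-1 per m2 m-2.
#' @param gpmax_floor Minimum gpmax, umol m-2 s-1 (bare/senesced canopy
#'   still has a trace of assimilating tissue; keeps campaigns fittable).
#' @param alpha_true Initial slope of the light response.
#' @param rref_true Base respiration at 10 deg C, umol m-2 s-1.
#' @param rref_seasonal Fractional seasonal amplification of rref at peak
#'   LAI (autotrophic respiration grows with biomass).
#' @param e0_true Temperature sensitivity, K.
#' @param ndvi_soil,ndvi_inf Bare-soil and asymptotic NDVI.
#' @param k_ext Extinction coefficient of the NDVI-LAI saturation curve,
#'   per unit LAI (larger = earlier saturation; ~1.4 for dense cereals).
#' @param rho850 Fixed near-infrared reflectance used to back out the red
#'   band from NDVI.
#' @param latitude,longitude Site coordinates, degrees.
#' @param par_noon_max Clear-sky noon PAR at the summer solstice,
#'   umol m-2 s-1.
#' @param t_base,t_seasonal_amp Annual mean and seasonal amplitude of
#'   daily-mean air temperature, deg C.
#' @param t_diurnal_amp Diurnal air-temperature amplitude, deg C.
#' @param par_noise SD of the daily clearness deviation (0 = always
#'   clear sky).
#' @param t_noise SD of the daily temperature offset, deg C.
#' @param conc_noise_ppm SD of CO2 concentration noise on chamber traces,
#'   umol mol-1.
#' @param refl_noise SD of additive per-band reflectance noise.
#' @param campaign_interval_d Days between chamber campaigns.
#' @param sampling_interval_d Days between LAI/spectral sampling dates
#'   (the daily merged table's resolution; spectral sampling is denser
#'   than the chamber campaigns it overlaps).
#' @param pressure_pa Ambient pressure, Pa.
#' @param seed Integer RNG seed; every stochastic draw derives from it.
#'
#' @return A validated list of class `season_config`.
#' @export
season_config <- function(crop_label = "winter wheat",
                          start_doy = 65, end_doy = 215,
                          lai_max = 4.0, lai_start = 1.0,
                          lai_peak_doy = 148,
                          lai_rise_rate = 0.12, lai_fall_rate = 0.10,
                          lai_plateau = 2.5, green_fraction_decline = 0.02,
                          gpmax_per_lai = 15, gpmax_floor = 0.5,
                          alpha_true = 0.06,
                          rref_true = 2.0, rref_seasonal = 0.5,
                          e0_true = 308.56,
                          ndvi_soil = 0.15, ndvi_inf = 0.92, k_ext = 1.4,
                          rho850 = 0.45,
                          latitude = 52.43, longitude = 16.3,
                          par_noon_max = 1600,
                          t_base = 8, t_seasonal_amp = 10.5,
                          t_diurnal_amp = 5,
                          par_noise = 0.2, t_noise = 1.5,
                          conc_noise_ppm = 0.3, refl_noise = 0.01,
                          campaign_interval_d = 14,
                          sampling_interval_d = 7,
                          pressure_pa = 101325,
                          seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(cfg$lai_max > 0,
            cfg$start_doy < cfg$lai_peak_doy, cfg$lai_peak_doy < cfg$end_doy,
            cfg$ndvi_soil < cfg$ndvi_inf, cfg$ndvi_inf <= 1,
            cfg$par_noise >= 0, cfg$t_noise >= 0,
            cfg$conc_noise_ppm >= 0, cfg$refl_noise >= 0,
            cfg$gpmax_per_lai > 0, cfg$alpha_true > 0, cfg$rref_true > 0)
  if (cfg$end_doy <= cfg$start_doy) stop("end_doy must exceed start_doy")
  stopifnot(cfg$lai_start >= 0, cfg$lai_start < cfg$lai_max)
  structure(cfg, class = "season_config")
}

#' Clear-sky noon PAR amplitude for a day
#'
#' Scales the solstice clear-sky noon PAR by the sine of the noon solar
#' elevation relative to its solstice value.
#' @noRd
.noon_amplitude <- function(doy, config) {
  rad <- pi / 180
  sin_elev <- function(d) {
    decl <- 23.45 * sin(2 * pi * (284 + d) / 365) * rad
    sin(config$latitude * rad) * sin(decl) +
      cos(config$latitude * rad) * cos(decl)
  }
  config$par_noon_max * pmax(0, sin_elev(doy)) / sin_elev(172)
}

#' Daily weather state (clearness factor and temperature offset)
#' @noRd
.daily_weather <- function(config) {
  days <- config$start_doy:config$end_doy
  .with_seed(config$seed, {
    clear <- pmax(0.2, 1 - abs(stats::rnorm(length(days), 0, config$par_noise)))
    t_eps <- stats::rnorm(length(days), 0, config$t_noise)
    if (config$par_noise == 0) clear <- rep(1, length(days))
    if (config$t_noise == 0) t_eps <- rep(0, length(days))
    data.frame(doy = days, clearness = clear, t_eps = t_eps)
  })
}

#' Instantaneous PAR and temperatures at an hour of a given day
#' @noRd
.driver_at <- function(doy, hour, weather_row, config) {
  win <- unname(day_window(doy, config$latitude))
  amp <- .noon_amplitude(doy, config) * weather_row$clearness
  par <- if (hour > win[1] && hour < win[2])
    unname(amp * sin(pi * (hour - win[1]) / (win[2] - win[1]))) else 0
  t_day <- config$t_base +
    config$t_seasonal_amp * sin(2 * pi * (doy - 112) / 365) + weather_row$t_eps
  t_air <- t_day + config$t_diurnal_amp * sin(2 * pi * (hour - 9) / 24)
  t_soil <- t_day + 0.4 * config$t_diurnal_amp * sin(2 * pi * (hour - 12) / 24)
  c(par = par, t_air_c = t_air, t_soil_c = t_soil)
}

#' Generate the continuous 30-min driver series
#'
#' PAR follows a half-sinusoid between the solar sunrise and sunset of
#' each day (exactly 0 at night), scaled by a per-day clearness factor;
#' air and soil temperature are seasonal plus diurnal sinusoids with a
#' per-day weather offset. Deterministic given the config seed.
#'
#' @param config A [season_config()].
#' @return Data.frame: time (doy + hour/24), doy, hour, par, t_air_c,
#'   t_soil_c, on a regular 30-min grid.
#' @export
generate_drivers <- function(config) {
  stopifnot(inherits(config, "season_config"))
  weather <- .daily_weather(config)
  days <- weather$doy
  hours <- seq(0, 23.5, by = 0.5)
  grid <- expand.grid(hour = hours, doy = days)
  di <- match(grid$doy, days)
  # vectorized twin of .driver_at (same formulas, same solar geometry)
  rad <- pi / 180
  decl <- 23.45 * sin(2 * pi * (284 + grid$doy) / 365)
  cosH <- pmin(1, pmax(-1, -tan(config$latitude * rad) * tan(decl * rad)))
  H <- acos(cosH) / rad
  sr <- 12 - H / 15
  ss <- 12 + H / 15
  amp <- .noon_amplitude(grid$doy, config) * weather$clearness[di]
  par <- ifelse(grid$hour > sr & grid$hour < ss,
                amp * sin(pi * (grid$hour - sr) / (ss - sr)), 0)
  t_day <- config$t_base +
    config$t_seasonal_amp * sin(2 * pi * (grid$doy - 112) / 365) +
    weather$t_eps[di]
  t_air <- t_day + config$t_diurnal_amp * sin(2 * pi * (grid$hour - 9) / 24)
  t_soil <- t_day +
    0.4 * config$t_diurnal_amp * sin(2 * pi * (grid$hour - 12) / 24)
  data.frame(time = grid$doy + grid$hour / 24, doy = grid$doy,
             hour = grid$hour, par = par, t_air_c = t_air, t_soil_c = t_soil)
}

#' Generate the daily LAI and green-LAI phenology
#'
#' Piecewise double-logistic total LAI: a logistic green-up from
#' `lai_start` at the season start to `lai_max` exactly at
#' `lai_peak_doy`, then a logistic
#' decline toward the `lai_plateau` of standing (partly dead) leaf area.
#' Green LAI equals total LAI before the peak and afterwards declines
#' linearly in fraction at `green_fraction_decline` per day, reflecting
#' chlorophyll loss while structural LAI persists.
#'
#' @param config A [season_config()].
#' @return Data.frame: doy, lai, lai_green.
#' @export
generate_lai_curve <- function(config) {
  stopifnot(inherits(config, "season_config"))
  d <- config$start_doy:config$end_doy
  peak <- config$lai_peak_doy
  plateau <- min(config$lai_plateau, 0.8 * config$lai_max)
  m1 <- (config$start_doy + peak) / 2
  m2 <- (peak + config$end_doy) / 2
  S <- function(x) 1 / (1 + exp(-config$lai_rise_rate * (x - m1)))
  U <- function(x) 1 / (1 + exp(config$lai_fall_rate * (x - m2)))
  lai <- ifelse(
    d <= peak,
    config$lai_start + (config$lai_max - config$lai_start) *
      (S(d) - S(config$start_doy)) / (S(peak) - S(config$start_doy)),
    plateau + (config$lai_max - plateau) * (U(d) - U(config$end_doy)) /
      (U(peak) - U(config$end_doy)))
  green_frac <- ifelse(d <= peak, 1,
                       pmax(0, 1 - config$green_fraction_decline * (d - peak)))
  data.frame(doy = d, lai = lai, lai_green = lai * green_frac)
}

#' Band reflectances from green LAI
#'
#' NDVI saturates exponentially with green LAI,
#' NDVI = ndvi_inf - (ndvi_inf - ndvi_soil) exp(-k_ext * lai_green);
#' the near-infrared band is held at `rho850` and the red band solved
#' from that NDVI; the 531/570 nm pair is near constant (PRI about -0.2).
#' Additive gaussian per-band noise, truncated at 0.
#'
#' @param lai_green Green LAI value(s), m2 m-2.
#' @param config A [season_config()].
#' @param seed_offset Integer added to the config seed for this draw.
#' @return Data.frame: rho531, rho570, rho670, rho850 (one row per input).
#' @export
generate_reflectance <- function(lai_green, config, seed_offset = 777L) {
  stopifnot(all(lai_green >= 0))
  nd <- config$ndvi_inf -
    (config$ndvi_inf - config$ndvi_soil) * exp(-config$k_ext * lai_green)
  rho850 <- rep(config$rho850, length(nd))
  rho670 <- rho850 * (1 - nd) / (1 + nd)
  rho531 <- rep(0.12, length(nd))
  rho570 <- rep(0.08, length(nd))
  if (config$refl_noise > 0) {
    .with_seed(config$seed + seed_offset, {
      n <- length(nd)
      rho850 <- pmax(0, rho850 + stats::rnorm(n, 0, config$refl_noise))
      rho670 <- pmax(0, rho670 + stats::rnorm(n, 0, config$refl_noise))
      rho531 <- pmax(0, rho531 + stats::rnorm(n, 0, config$refl_noise))
      rho570 <- pmax(0, rho570 + stats::rnorm(n, 0, config$refl_noise))
    })
  }
  data.frame(rho531 = rho531, rho570 = rho570,
             rho670 = rho670, rho850 = rho850)
}

#' Campaign days of a season
#' @param config A [season_config()].
#' @return Integer vector of campaign days of year.
#' @export
campaign_days <- function(config) {
  seq(config$start_doy + 3, config$end_doy - 2, by = config$campaign_interval_d)
}

#' LAI/spectral sampling days of a season
#' @param config A [season_config()].
#' @return Integer vector of sampling days of year.
#' @export
sampling_days <- function(config) {
  seq(config$start_doy + 3, config$end_doy - 2, by = config$sampling_interval_d)
}

#' True flux-model parameters at the campaign anchors
#'
#' gpmax is tied to green LAI (gpmax_per_lai * greenLAI, floored at
#' gpmax_floor), rref carries a small seasonal biomass term, and alpha
#' and e0 are constant over the season.
#'
#' @param config A [season_config()].
#' @param lai Output of [generate_lai_curve()] (recomputed when NULL).
#' @return Data.frame: doy, rref, e0, alpha, gpmax (one row per campaign).
#' @export
true_campaign_params <- function(config, lai = NULL) {
  if (is.null(lai)) lai <- generate_lai_curve(config)
  cd <- campaign_days(config)
  row <- match(cd, lai$doy)
  data.frame(
    doy = cd,
    rref = config$rref_true *
      (1 + config$rref_seasonal * lai$lai[row] / config$lai_max),
    e0 = config$e0_true,
    alpha = config$alpha_true,
    gpmax = pmax(config$gpmax_floor, config$gpmax_per_lai * lai$lai_green[row]))
}

#' Generate the full truth bundle for a season
#'
#' Drivers, LAI phenology, campaign-anchor parameters, the 30-min
#' parameter trajectories (linear between campaign anchors at 12:00, held
#' at the ends -- the same convention the partitioning stage uses), and
#' the true 30-min GEP/Reco/NEP series driven by them. NEP = GEP - Reco
#' at every step and GEP = 0 wherever PAR = 0, by construction.
#'
#' @param config A [season_config()].
#' @return List of class `truth_bundle`: config, drivers, lai, weather,
#'   params_true (campaign anchors), params30, fluxes30.
#' @export
generate_truth <- function(config) {
  drivers <- generate_drivers(config)
  lai <- generate_lai_curve(config)
  anchors <- true_campaign_params(config, lai)
  params30 <- interpolate_params(anchors, drivers$time)
  fluxes30 <- reconstruct_30min(params30, drivers)
  structure(list(config = config, drivers = drivers, lai = lai,
                 weather = .daily_weather(config),
                 params_true = anchors, params30 = params30,
                 fluxes30 = fluxes30),
            class = "truth_bundle")
}

#' Simulate the chamber closures of one campaign day
#'
#' Between 5 and 12 paired closures (count scaled by daylength) spread
#' from just after sunrise to late afternoon. Each pair is a transparent
#' 120 s closure (NEP) and an opaque 180 s closure (Reco), both sampled
#' at 1 Hz. The concentration trace is linear,
#' C(t) = C0 + slope * t + noise, with slope = F * A * Mv / V and the
#' chamber sign convention: canopy uptake draws the transparent-chamber
#' concentration down, respiration drives the opaque one up. True fluxes
#' come from that day's anchor parameter values (parameters are treated
#' as constant within a field day).
#'
#' @param doy Campaign day of year; must lie inside the season.
#' @param truth A [generate_truth()] bundle.
#' @param n_closures Override the daylength-based closure count (still
#'   clamped to 5-12).
#' @return List of [chamber_closure()] objects with a `truth` attribute:
#'   a data.frame of the true flux behind every closure.
#' @export
generate_closures <- function(doy, truth, n_closures = NULL) {
  stopifnot(inherits(truth, "truth_bundle"))
  config <- truth$config
  if (doy < config$start_doy || doy > config$end_doy)
    stop("truth bundle does not cover doy ", doy)
  win <- day_window(doy, config$latitude)
  daylen <- win[2] - win[1]
  n <- if (is.null(n_closures)) round(0.7 * daylen) else n_closures
  n <- min(12, max(5, n))
  times <- seq(win[1] + 0.75, min(win[2] - 1.5, 17.5), length.out = n)
  wrow <- truth$weather[truth$weather$doy == doy, ]
  # day-constant parameters: the interpolated trajectory at the 12:00 anchor
  p <- truth$params30[which.min(abs(truth$params30$time - (doy + 0.5))), ]
  closures <- list()
  truth_rows <- list()
  .with_seed(config$seed + doy, {
    for (i in seq_len(n)) {
      drv <- .driver_at(doy, times[i], wrow, config)
      gep <- light_response(max(drv["par"], 0), p$alpha, p$gpmax)
      if (drv["par"] == 0) gep <- 0
      reco <- reco_model(drv["t_soil_c"], p$rref, p$e0)
      nep <- gep - reco
      mv <- molar_volume(drv["t_air_c"], config$pressure_pa)
      geom <- .CHAMBER_A * mv / .CHAMBER_V
      for (kind in c("transparent", "opaque")) {
        dur <- if (kind == "transparent") 120 else 180
        f_raw <- if (kind == "transparent") -nep else reco
        tt <- 0:(dur - 1)
        co2 <- 400 + f_raw * geom * tt
        if (config$conc_noise_ppm > 0)
          co2 <- co2 + stats::rnorm(dur, 0, config$conc_noise_ppm)
        id <- sprintf("d%03d_c%02d_%s", doy, i, substr(kind, 1, 1))
        closures[[id]] <- chamber_closure(
          closure_id = id, plot_id = config$crop_label, chamber_kind = kind,
          t_s = tt, co2_ppm = co2,
          t_air_c = unname(drv["t_air_c"]),
          pressure_pa = config$pressure_pa,
          par = unname(drv["par"]), t_soil_c = unname(drv["t_soil_c"]))
        truth_rows[[id]] <- data.frame(
          closure_id = id, doy = doy, hour = times[i], chamber_kind = kind,
          flux_true = if (kind == "transparent") nep else reco,
          gep_true = gep, reco_true = reco,
          par = unname(drv["par"]), stringsAsFactors = FALSE)
      }
    }
  })
  attr(closures, "truth") <- do.call(rbind, truth_rows)
  closures
}

#' Generate a complete synthetic season
#'
#' Truth bundle plus the chamber closures of every campaign day and the
#' daily merged table (true GEP_d, PAR_d, LAI and vegetation indices at
#' the spectral sampling dates) that feeds the regression and
#' phase-analysis stages directly.
#'
#' @param config A [season_config()].
#' @param year Calendar year label carried through the daily table.
#' @return List of class `synthetic_season`: truth, closures (list named
#'   by campaign doy), daily (data.frame).
#' @export
generate_season <- function(config, year = 2011L) {
  truth <- generate_truth(config)
  cd <- campaign_days(config)
  closures <- lapply(cd, generate_closures, truth = truth)
  names(closures) <- cd
  sd <- sampling_days(config)
  lai_row <- match(sd, truth$lai$doy)
  refl <- generate_reflectance(truth$lai$lai_green[lai_row], config)
  vis <- vi_table(refl$rho531, refl$rho570, refl$rho670, refl$rho850)
  daily <- data.frame(
    crop = config$crop_label, year = year, doy = sd,
    gep_d = vapply(sd, function(d)
      daily_gep(truth$fluxes30, d, day_window(d, config$latitude)), 0),
    par_d = vapply(sd, function(d)
      daily_par(truth$drivers, d, day_window(d, config$latitude)), 0),
    lai = truth$lai$lai[lai_row],
    lai_green = truth$lai$lai_green[lai_row])
  daily <- cbind(daily, vis)
  structure(list(truth = truth, closures = closures, daily = daily),
            class = "synthetic_season")
}
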