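# Campaign-wise flux model fitting, parameter interpolation, 30-min
# GEP/Reco/NEP reconstruction and daily aggregation.
#
# One "campaign" is a field day of repeated chamber closures. From each
# campaign's QC-passed fluxes two sub-models are fitted:
#   Reco(T)  = rref * exp(e0 * (1/(Tref-T0) - 1/(T_K-T0)))   (Lloyd-Taylor)
#   GEP(PAR) = alpha * PAR * gpmax / (alpha * PAR + gpmax)   (Michaelis-Menten)
# Parameters are interpolated linearly between campaigns (anchored at
# 12:00) and driven with the continuous 30-min PAR/temperature series.
#
# Time axis convention: numeric `time` = day-of-year + hour/24 (local
# solar time), so one season fits on a single continuous axis.

#' Lloyd-Taylor reference and zero-activation temperatures, K
#' @noRd
.LT_TREF <- 283.15
.LT_T0 <- 227.13

#' Grams of carbon per mol CO2
#' @noRd
.GC_PER_UMOL <- 12.011e-6

#' Lloyd-Taylor ecosystem respiration
#'
#' Arrhenius-type temperature response
#' Reco = rref * exp(e0 * (1/(Tref - T0) - 1/(T_K - T0))) with the
#' canonical constants Tref = 283.15 K (10 deg C) and T0 = 227.13 K.
#' `rref` is the respiration at the reference temperature and `e0` the
#' temperature-sensitivity parameter (K).
#'
#' @param t_c Temperature, deg C.
#' @param rref Respiration at 10 deg C, umol CO2 m-2 s-1.
#' @param e0 Temperature sensitivity, K.
#' @return Reco, umol CO2 m-2 s-1.
#' @export
reco_model <- function(t_c, rref, e0) {
  t_k <- t_c + 273.15
  if (any(t_k <= .LT_T0)) stop("temperature at or below Lloyd-Taylor T0")
  rref * exp(e0 * (1 / (.LT_TREF - .LT_T0) - 1 / (t_k - .LT_T0)))
}

#' Michaelis-Menten (rectangular hyperbola) light response
#'
#' GEP = alpha * PAR * gpmax / (alpha * PAR + gpmax): initial slope
#' `alpha` (umol CO2 per umol photons) and asymptote `gpmax`
#' (umol CO2 m-2 s-1). GEP is uptake-positive.
#'
#' @param par PAR, umol m-2 s-1 (>= 0).
#' @param alpha Initial slope of the light response.
#' @param gpmax Asymptotic GEP at saturating light.
#' @return GEP, umol CO2 m-2 s-1.
#' @export
light_response <- function(par, alpha, gpmax) {
  stopifnot(alpha > 0, gpmax > 0)
  if (any(par < 0)) stop("PAR must be non-negative")
  alpha * par * gpmax / (alpha * par + gpmax)
}

#' Fit the Lloyd-Taylor model to one campaign's respiration fluxes
#'
#' Bounded nonlinear least squares (Levenberg-Marquardt) of Reco against
#' temperature; rref in (0, 50], e0 in [50, 450]. When the temperature
#' span is below `min_t_span` the two parameters are not separable, so
#' e0 is fixed at 308.56 K and only rref is fitted (closed form: the
#' mean measured Reco mapped back to the reference temperature).
#'
#' @param reco Measured respiration fluxes, umol m-2 s-1 (release-positive).
#' @param t_c Temperatures paired with `reco`, deg C.
#' @param min_t_span Minimum temperature range (deg C) to fit e0; default 2.
#' @param e0_fixed Fallback e0 when the span is too small; default 308.56.
#' @return List: rref, e0, n, sse, fallback (logical).
#' @export
fit_reco_campaign <- function(reco, t_c, min_t_span = 2, e0_fixed = 308.56) {
  ok <- is.finite(reco) & is.finite(t_c)
  reco <- reco[ok]; t_c <- t_c[ok]
  if (length(reco) < 4)
    stop("campaign unfittable: fewer than 4 respiration fluxes")
  span <- diff(range(t_c))
  if (span < min_t_span) {
    # closed form: rref = mean(Reco_i / g(T_i)) with g the unit-rref response
    g <- reco_model(t_c, 1, e0_fixed)
    rref <- mean(reco / g)
    sse <- sum((reco - reco_model(t_c, rref, e0_fixed))^2)
    return(list(rref = rref, e0 = e0_fixed, n = length(reco), sse = sse,
                fallback = TRUE))
  }
  dat <- data.frame(reco = reco, t_c = t_c)
  fit <- minpack.lm::nlsLM(
    reco ~ reco_model(t_c, rref, e0), data = dat,
    start = list(rref = max(mean(reco), 0.1), e0 = e0_fixed),
    lower = c(rref = 1e-6, e0 = 50), upper = c(rref = 50, e0 = 450),
    control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14,
                                         ptol = 1e-14))
  cf <- stats::coef(fit)
  list(rref = unname(cf["rref"]), e0 = unname(cf["e0"]), n = length(reco),
       sse = sum(stats::residuals(fit)^2), fallback = FALSE)
}

#' Fit the Michaelis-Menten light response to one campaign's GEP fluxes
#'
#' Bounded nonlinear least squares with a small multi-start: three fixed
#' initial (alpha, gpmax) pairs, the fit with the smallest SSE wins and
#' ties go to the smaller gpmax (the less extrapolated asymptote).
#' Bounds: alpha in (0, 0.3], gpmax in (0, 120].
#'
#' @param gep GEP values (uptake-positive), umol m-2 s-1.
#' @param par PAR paired with `gep`, umol m-2 s-1.
#' @param min_par_span Minimum PAR range needed to constrain the
#'   hyperbola; default 200 umol m-2 s-1.
#' @return List: alpha, gpmax, n, sse, degenerate (logical; TRUE when the
#'   response carries no light signal and the fit sits at a bound).
#' @export
fit_light_campaign <- function(gep, par, min_par_span = 200) {
  ok <- is.finite(gep) & is.finite(par)
  gep <- gep[ok]; par <- par[ok]
  if (length(gep) < 4)
    stop("campaign unfittable: fewer than 4 GEP points")
  if (diff(range(par)) < min_par_span)
    stop("campaign unfittable: PAR span below ", min_par_span)
  dat <- data.frame(gep = gep, par = par)
  starts <- list(c(alpha = 0.02, gpmax = 15),
                 c(alpha = 0.05, gpmax = 30),
                 c(alpha = 0.10, gpmax = 60))
  best <- NULL
  for (s in starts) {
    fit <- try(minpack.lm::nlsLM(
      gep ~ light_response(par, alpha, gpmax), data = dat,
      start = as.list(s),
      lower = c(alpha = 1e-6, gpmax = 1e-3),
      upper = c(alpha = 0.3, gpmax = 120),
      control = minpack.lm::nls.lm.control(maxiter = 300, ftol = 1e-14,
                                           ptol = 1e-14)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    cand <- list(alpha = unname(stats::coef(fit)["alpha"]),
                 gpmax = unname(stats::coef(fit)["gpmax"]),
                 sse = sum(stats::residuals(fit)^2))
    if (is.null(best) || cand$sse < best$sse - 1e-12 ||
        (abs(cand$sse - best$sse) <= 1e-12 && cand$gpmax < best$gpmax))
      best <- cand
  }
  if (is.null(best)) stop("light-response fit failed from all starts")
  degenerate <- best$gpmax <= 1e-2 || best$alpha <= 1e-5
  list(alpha = best$alpha, gpmax = best$gpmax, n = length(gep),
       sse = best$sse, degenerate = degenerate)
}

#' Observed GEP at the NEP measurement times
#'
#' Evaluates the fitted respiration model at each NEP measurement's
#' temperature and adds it to the measured NEP: GEP = NEP + Reco.
#'
#' @param nep Measured NEP (uptake-positive), umol m-2 s-1.
#' @param t_c Temperature at the NEP measurement times, deg C.
#' @param rref,e0 Fitted Lloyd-Taylor parameters for the campaign.
#' @return Vector of observed GEP, umol m-2 s-1.
#' @export
gep_observed <- function(nep, t_c, rref, e0) {
  if (any(!is.finite(t_c))) stop("missing temperature at NEP measurement")
  nep + reco_model(t_c, rref, e0)
}

#' Fit both flux sub-models for one campaign
#'
#' Convenience wrapper taking the QC-passed flux records of one field day:
#' fits Lloyd-Taylor on the opaque (Reco) fluxes, derives observed GEP for
#' the transparent (NEP) fluxes, and fits the light response.
#'
#' @param fluxes Data.frame with columns flux_kind (NEP/Reco), flux, par,
#'   and a temperature column.
#' @param campaign_doy Day of year of the campaign.
#' @param temp_col Which temperature drives respiration: `"t_soil_c"`
#'   (default) or `"t_air_c"`; falls back to air when soil is missing.
#' @return One-row data.frame of campaign parameters:
#'   doy, rref, e0, alpha, gpmax, n_reco, n_gep, sse_reco, sse_gep.
#' @export
fit_campaign <- function(fluxes, campaign_doy, temp_col = "t_soil_c") {
  temp <- fluxes[[temp_col]]
  if (is.null(temp) || all(!is.finite(temp))) temp <- fluxes$t_air_c
  rec <- fluxes$flux_kind == "Reco"
  rfit <- fit_reco_campaign(fluxes$flux[rec], temp[rec])
  nep_i <- fluxes$flux_kind == "NEP"
  gep <- gep_observed(fluxes$flux[nep_i], temp[nep_i], rfit$rref, rfit$e0)
  lfit <- fit_light_campaign(gep, fluxes$par[nep_i])
  data.frame(doy = campaign_doy, rref = rfit$rref, e0 = rfit$e0,
             alpha = lfit$alpha, gpmax = lfit$gpmax,
             n_reco = rfit$n, n_gep = lfit$n,
             sse_reco = rfit$sse, sse_gep = lfit$sse)
}

#' Interpolate campaign parameters onto a 30-min grid
#'
#' Each parameter is interpolated linearly in time between consecutive
#' campaigns, anchored at 12:00 of the campaign day, and held constant
#' before the first and after the last campaign.
#'
#' @param campaigns Data.frame with columns doy, rref, e0, alpha, gpmax
#'   (one row per campaign, as from [fit_campaign()]).
#' @param time Numeric target times (day-of-year + hour/24).
#' @return Data.frame: time, rref, e0, alpha, gpmax.
#' @export
interpolate_params <- function(campaigns, time) {
  if (nrow(campaigns) < 1) stop("no fittable campaigns to interpolate")
  campaigns <- campaigns[order(campaigns$doy), , drop = FALSE]
  anchor <- campaigns$doy + 0.5
  interp1 <- function(y) {
    if (length(anchor) == 1) return(rep(y, length(time)))
    stats::approx(anchor, y, xout = time, rule = 2)$y
  }
  data.frame(time = time,
             rref = interp1(campaigns$rref),
             e0 = interp1(campaigns$e0),
             alpha = interp1(campaigns$alpha),
             gpmax = interp1(campaigns$gpmax))
}

#' Reconstruct continuous 30-min GEP, Reco and NEP
#'
#' Drives the fitted models with the continuous PAR and temperature
#' series: gep = light_response(par), reco = reco_model(T), and
#' nep = gep - reco at every step. GEP is exactly 0 wherever PAR = 0.
#'
#' @param params Parameter series from [interpolate_params()]; its `time`
#'   must equal the drivers' `time`.
#' @param drivers Data.frame with time, par and a temperature column.
#' @param temp_col Temperature column driving respiration; default
#'   `"t_soil_c"`, falling back to `"t_air_c"` when absent.
#' @return Data.frame: time, gep, reco, nep.
#' @export
reconstruct_30min <- function(params, drivers, temp_col = "t_soil_c") {
  if (nrow(params) != nrow(drivers) ||
      max(abs(params$time - drivers$time)) > 1e-9)
    stop("parameter and driver grids do not match")
  temp <- drivers[[temp_col]]
  if (is.null(temp)) temp <- drivers$t_air_c
  gep <- ifelse(drivers$par > 0,
                params$alpha * drivers$par * params$gpmax /
                  (params$alpha * drivers$par + params$gpmax),
                0)
  reco <- reco_model(temp, params$rref, params$e0)
  data.frame(time = drivers$time, gep = gep, reco = reco, nep = gep - reco)
}

#' Sunrise and sunset for a day of year
#'
#' Standard solar-geometry approximation in local solar time: declination
#' delta = 23.45 deg * sin(2 pi (284 + doy)/365), hour angle
#' H = acos(-tan(lat) tan(delta)), sunrise = 12 - H/15 h, sunset = 12 +
#' H/15 h. Alternatively (`mode = "par"`) the window is taken from the
#' driver series itself: first to last 30-min step with PAR above
#' `par_threshold`.
#'
#' @param doy Day of year (1-365).
#' @param latitude Site latitude, degrees (|lat| < 66.5; polar days/nights
#'   unsupported).
#' @param mode `"solar"` (default) or `"par"`.
#' @param drivers Driver data.frame (required for `mode = "par"`).
#' @param par_threshold PAR threshold for the `"par"` mode, umol m-2 s-1.
#' @return Numeric c(sunrise, sunset), hours of local solar time.
#' @export
day_window <- function(doy, latitude, mode = c("solar", "par"),
                       drivers = NULL, par_threshold = 1) {
  mode <- match.arg(mode)
  if (mode == "par") {
    if (is.null(drivers)) stop("PAR mode needs a driver series")
    day <- drivers[floor(drivers$time) == doy & drivers$par > par_threshold, ]
    if (nrow(day) == 0) stop("no daylight PAR found on doy ", doy)
    h <- (day$time - doy) * 24
    return(c(sunrise = min(h), sunset = max(h) + 0.5))
  }
  if (abs(latitude) >= 66.5) stop("polar latitudes unsupported")
  decl <- 23.45 * sin(2 * pi * (284 + doy) / 365)
  rad <- pi / 180
  cosH <- -tan(latitude * rad) * tan(decl * rad)
  cosH <- min(1, max(-1, cosH))
  H <- acos(cosH) / rad
  c(sunrise = 12 - H / 15, sunset = 12 + H / 15)
}

#' Daily GEP sum over the daylight window
#'
#' GEP_d = sum of all 30-min GEP fluxes between sunrise and sunset,
#' converted to grams of CO2 carbon:
#' sum(gep_i) * 1800 s * 12.011e-6 gC umol-1. A step belongs to the
#' window when its midpoint falls in [sunrise, sunset).
#'
#' @param series 30-min flux series (time, gep) for one or more days.
#' @param doy Day of year to aggregate.
#' @param window c(sunrise, sunset) in hours, from [day_window()].
#' @return GEP_d, gCO2-C m-2 d-1.
#' @export
daily_gep <- function(series, doy, window) {
  h <- (series$time - doy) * 24
  sel <- floor(series$time) == doy
  mid <- h + 0.25
  inwin <- sel & mid >= window[1] & mid < window[2]
  if (!any(inwin)) return(0)
  # the day's 30-min grid must be gap-free inside the window
  hh <- sort(h[inwin])
  if (length(hh) > 1 && any(abs(diff(hh) - 0.5) > 1e-9))
    stop("gaps in the 30-min series inside the daylight window of doy ", doy)
  sum(series$gep[inwin]) * 1800 * .GC_PER_UMOL
}

#' Mean daylight PAR for one day
#'
#' Arithmetic mean of the 30-min PAR values whose step midpoint lies in
#' the sunrise-sunset window; nighttime steps are never included.
#'
#' @param drivers Driver series (time, par).
#' @inheritParams daily_gep
#' @return PAR_d, umol m-2 s-1.
#' @export
daily_par <- function(drivers, doy, window) {
  h <- (drivers$time - doy) * 24
  mid <- h + 0.25
  inwin <- floor(drivers$time) == doy & mid >= window[1] & mid < window[2]
  if (!any(inwin)) stop("no driver steps inside the daylight window of doy ", doy)
  mean(drivers$par[inwin])
}
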