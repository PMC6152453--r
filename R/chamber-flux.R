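# Per-closure CO2 flux computation from closed-chamber concentration traces.
#
# A "closure" is one deployment of a transparent (NEP) or opaque (Reco)
# chamber: a ~120-180 s CO2 concentration series recorded at ~1 Hz together
# with chamber air temperature, pressure, PAR and the chamber geometry.

#' Universal gas constant, J mol-1 K-1
#' @noRd
.R_GAS <- 8.31446

#' Default chamber geometry: 0.296 m3 chamber on a 0.75 x 0.75 m collar
#' @noRd
.CHAMBER_V <- 0.296
.CHAMBER_A <- 0.5625

#' Construct a chamber closure record
#'
#' Bundles one chamber deployment's concentration trace with its
#' environmental readings and geometry, validating the invariants the
#' flux computation relies on.
#'
#' @param closure_id Character id of the closure.
#' @param plot_id Character id of the measurement plot.
#' @param chamber_kind `"transparent"` (NEP) or `"opaque"` (Reco).
#' @param t_s Numeric vector, seconds from closure start; strictly increasing.
#' @param co2_ppm CO2 dry mole fraction series, umol mol-1; same length as `t_s`.
#' @param t_air_c Mean chamber headspace air temperature during closure, deg C.
#' @param pressure_pa Air pressure, Pa.
#' @param par Mean PAR during the closure, umol m-2 s-1.
#' @param t_soil_c Soil temperature, deg C (used by the respiration model).
#' @param volume_m3 Chamber volume V, m3.
#' @param area_m2 Enclosed soil area A, m2.
#'
#' @return An object of class `chamber_closure` (a list).
#' @export
chamber_closure <- function(closure_id, plot_id = "p1",
                            chamber_kind = c("transparent", "opaque"),
                            t_s, co2_ppm, t_air_c, pressure_pa = 101325,
                            par = NA_real_, t_soil_c = NA_real_,
                            volume_m3 = .CHAMBER_V, area_m2 = .CHAMBER_A) {
  chamber_kind <- match.arg(chamber_kind)
  if (length(t_s) != length(co2_ppm))
    stop("closure ", closure_id, ": t_s and co2_ppm lengths differ")
  if (length(t_s) < 10)
    stop("closure ", closure_id, ": fewer than 10 samples")
  if (any(diff(t_s) <= 0))
    stop("closure ", closure_id, ": timestamps not strictly increasing")
  if (volume_m3 <= 0 || area_m2 <= 0)
    stop("closure ", closure_id, ": chamber volume and area must be positive")
  structure(list(
    closure_id = closure_id, plot_id = plot_id, chamber_kind = chamber_kind,
    t_s = as.numeric(t_s), co2_ppm = as.numeric(co2_ppm),
    t_air_c = t_air_c, pressure_pa = pressure_pa, par = par,
    t_soil_c = t_soil_c, volume_m3 = volume_m3, area_m2 = area_m2
  ), class = "chamber_closure")
}

#' OLS slope of the concentration trace
#'
#' Fits CO2 concentration against time by ordinary least squares and
#' returns the slope (dC/dt) and the coefficient of determination of
#' that fit. A trace with zero concentration variance gets slope 0 and,
#' by convention, r2 = 0 so the QC filter flags it deterministically.
#'
#' @param closure A [chamber_closure()].
#' @param trim_s Seconds discarded from the start of the trace to let the
#'   headspace mix after chamber placement; default 10 s.
#'
#' @return List with `slope` (umol mol-1 s-1), `r2`, and `n` points used.
#' @export
fit_concentration_slope <- function(closure, trim_s = 10) {
  stopifnot(inherits(closure, "chamber_closure"))
  keep <- closure$t_s >= trim_s
  t_s <- closure$t_s[keep]
  co2 <- closure$co2_ppm[keep]
  if (length(t_s) < 10)
    stop("closure ", closure$closure_id, ": fewer than 10 samples after trimming")
  if (stats::var(co2) == 0)
    return(list(slope = 0, r2 = 0, n = length(t_s)))
  fit <- stats::lm(co2 ~ t_s)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((co2 - mean(co2))^2)
  list(slope = unname(stats::coef(fit)[2]),
       r2 = 1 - ss_res / ss_tot,
       n = length(t_s))
}

#' Molar volume of air
#'
#' Ideal-gas molar volume Mv = R T / p at the chamber air temperature and
#' pressure, used to convert the concentration slope to an areal flux.
#'
#' @param t_air_c Air temperature, deg C.
#' @param pressure_pa Pressure, Pa.
#' @return Molar volume, m3 mol-1.
#' @export
#' @examples
#' molar_volume(0, 101325)   # 0.022414, the standard molar volume
molar_volume <- function(t_air_c, pressure_pa = 101325) {
  if (any(pressure_pa <= 0)) stop("pressure must be positive")
  if (any(t_air_c <= -100)) stop("implausible chamber air temperature")
  .R_GAS * (t_air_c + 273.15) / pressure_pa
}

#' CO2 flux from a concentration slope
#'
#' F = dC/dt * V / (A * Mv): the chamber-headspace concentration change
#' scaled by chamber volume, collar area and the molar volume of air.
#' The raw flux is release-positive (concentration rising in the
#' chamber). For a transparent chamber the ecological NEP is
#' uptake-positive, i.e. NEP = -F_raw; for an opaque chamber
#' Reco = F_raw.
#'
#' @param slope Concentration slope, umol mol-1 s-1.
#' @param volume_m3 Chamber volume V, m3.
#' @param area_m2 Collar area A, m2.
#' @param mv Molar volume of air, m3 mol-1 (see [molar_volume()]).
#' @return Flux, umol CO2 m-2 s-1, release-positive.
#' @export
compute_flux <- function(slope, volume_m3 = .CHAMBER_V, area_m2 = .CHAMBER_A, mv) {
  if (any(volume_m3 <= 0) || any(area_m2 <= 0) || any(mv <= 0))
    stop("volume, area and molar volume must all be positive")
  slope * volume_m3 / (area_m2 * mv)
}

#' Compute the flux record for one closure
#'
#' Runs the slope fit, converts to an areal flux with the closure's own
#' geometry and air state, and applies the sign convention: transparent
#' closures yield uptake-positive NEP, opaque closures release-positive
#' Reco.
#'
#' @param closure A [chamber_closure()].
#' @param trim_s Passed to [fit_concentration_slope()].
#' @return One-row data.frame: closure_id, plot_id, flux_kind (NEP/Reco),
#'   flux (sign-converted), raw_slope, r2, n, par, t_air_c, t_soil_c.
#' @export
closure_flux <- function(closure, trim_s = 10) {
  sl <- fit_concentration_slope(closure, trim_s = trim_s)
  mv <- molar_volume(closure$t_air_c, closure$pressure_pa)
  f_raw <- compute_flux(sl$slope, closure$volume_m3, closure$area_m2, mv)
  kind <- if (closure$chamber_kind == "transparent") "NEP" else "Reco"
  flux <- if (kind == "NEP") -f_raw else f_raw
  data.frame(
    closure_id = closure$closure_id, plot_id = closure$plot_id,
    flux_kind = kind, flux = flux, raw_slope = sl$slope,
    r2 = sl$r2, n = sl$n, par = closure$par,
    t_air_c = closure$t_air_c, t_soil_c = closure$t_soil_c,
    stringsAsFactors = FALSE
  )
}

#' Quality-control filter on fitted fluxes
#'
#' Fluxes whose concentration fit has r2 below `r2_min` are excluded,
#' except that near-zero fluxes (|F| <= `near_zero_abs`) are only flagged
#' for review: a flat trace on a calm night is a genuine near-zero flux,
#' not a failed fit, and discarding those would bias respiration low.
#' Reviewed near-zero fluxes are retained by default.
#'
#' @param records Data.frame of flux records as from [closure_flux()].
#' @param r2_min Exclusion threshold on r2; default 0.8.
#' @param near_zero_abs Absolute flux below which a poor fit is treated as
#'   a plausible near-zero flux, umol m-2 s-1; default 0.5.
#' @param keep_near_zero Retain `near_zero_review` records in the `pass`
#'   subset logical? Default TRUE.
#' @return `records` with a `qc_flag` column (`pass`, `excluded_r2`,
#'   `near_zero_review`) and a logical `qc_pass`.
#' @export
qc_filter <- function(records, r2_min = 0.8, near_zero_abs = 0.5,
                      keep_near_zero = TRUE) {
  stopifnot(r2_min > 0, r2_min <= 1)
  flag <- ifelse(records$r2 >= r2_min, "pass",
          ifelse(abs(records$flux) <= near_zero_abs, "near_zero_review",
                 "excluded_r2"))
  records$qc_flag <- flag
  records$qc_pass <- flag == "pass" | (keep_near_zero & flag == "near_zero_review")
  records
}
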