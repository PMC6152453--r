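# Vegetation indices from 4-band canopy radiometry (531, 570, 670, 850 nm).
#
# Two input modes are supported: band reflectances directly, or raw
# dual-radiometer readings (incident channels in umol m-2 s-1, reflected
# channels in nanoamps) combined with the sensor pair's ratio sensitivity.

#' Normalized difference from raw dual-radiometer readings
#'
#' VI = (Z R1r Y - R2r X) / (Z R1r Y + R2r X), where R1r and R2r are the
#' reflected-signal readings of the two bands, X and Y the corresponding
#' incident readings, and Z the ratio sensitivity calibrating the two
#' reflected channels against each other. For NDVI/SAVI the band pair is
#' R1 = 850 nm, R2 = 670 nm; for PRI it is R1 = 570 nm, R2 = 531 nm.
#'
#' @param r1r,r2r Reflected readings of bands R1 and R2 (nanoamps).
#' @param x,y Incident readings paired with R1 and R2 respectively
#'   (umol m-2 s-1); `y` calibrates `r1r` and `x` calibrates `r2r`.
#' @param z Ratio sensitivity of reflected R1r:R2r.
#' @return The normalized-difference value in [-1, 1].
#' @export
vi_from_raw <- function(r1r, r2r, x, y, z = 1) {
  if (any(x <= 0) || any(y <= 0)) stop("incident readings must be positive")
  num <- z * r1r * y - r2r * x
  den <- z * r1r * y + r2r * x
  if (any(den == 0)) stop("zero denominator in raw-reading VI")
  num / den
}

#' Normalized Difference Vegetation Index
#'
#' NDVI = (rho850 - rho670) / (rho850 + rho670).
#'
#' @param rho850,rho670 Near-infrared and red reflectance in [0, 1].
#' @return NDVI in [-1, 1].
#' @export
ndvi <- function(rho850, rho670) {
  den <- rho850 + rho670
  if (any(den == 0)) stop("zero denominator in NDVI")
  (rho850 - rho670) / den
}

#' Soil Adjusted Vegetation Index
#'
#' SAVI = (rho850 - rho670) / (rho850 + rho670 + L) * (1 + L), with soil
#' adjustment factor L (canonical 0.5 for intermediate vegetation cover;
#' L = 0 reduces to NDVI).
#'
#' @inheritParams ndvi
#' @param L Soil adjustment factor, default 0.5.
#' @return SAVI value.
#' @export
savi <- function(rho850, rho670, L = 0.5) {
  den <- rho850 + rho670 + L
  if (any(den == 0)) stop("zero denominator in SAVI")
  (rho850 - rho670) / den * (1 + L)
}

#' Photochemical Reflectance Index
#'
#' PRI = (rho570 - rho531) / (rho570 + rho531), a light-use-efficiency
#' proxy built on the xanthophyll-sensitive 531 nm band.
#'
#' @param rho570,rho531 Reflectance in the 570 and 531 nm bands.
#' @return PRI in [-1, 1].
#' @export
pri <- function(rho570, rho531) {
  den <- rho570 + rho531
  if (any(den == 0)) stop("zero denominator in PRI")
  (rho570 - rho531) / den
}

#' Wide Dynamic Range Vegetation Index from NDVI
#'
#' WDRVI = [(a+1) NDVI + (a-1)] / [(a-1) NDVI + (a+1)] with weight
#' a (default 0.2). The Moebius transform down-weights the NIR signal,
#' linearizing the index across the moderate-to-high biomass range where
#' NDVI saturates; it is strictly increasing in NDVI for a in (0, 1) and
#' maps NDVI = 1 to 1.
#'
#' @param ndvi NDVI value(s) in [-1, 1].
#' @param alpha Weighting coefficient a, default 0.2.
#' @return WDRVI in [-1, 1].
#' @export
wdrvi_from_ndvi <- function(ndvi, alpha = 0.2) {
  den <- (alpha - 1) * ndvi + (alpha + 1)
  if (any(den == 0)) stop("zero denominator in WDRVI transform")
  ((alpha + 1) * ndvi + (alpha - 1)) / den
}

#' Scaled WDRVI
#'
#' sWDRVI = (WDRVI + 1) / 2, rescaling WDRVI to [0, 1] so seasonal
#' courses stay in positive numbers.
#'
#' @param wdrvi WDRVI value(s) in [-1, 1].
#' @return sWDRVI in [0, 1].
#' @export
swdrvi <- function(wdrvi) {
  if (any(wdrvi < -1 - 1e-12) || any(wdrvi > 1 + 1e-12))
    stop("WDRVI outside [-1, 1]")
  (wdrvi + 1) / 2
}

#' All indices from band reflectances
#'
#' @param rho531,rho570,rho670,rho850 Band reflectances in [0, 1].
#' @param savi_L SAVI soil factor.
#' @param wdrvi_alpha WDRVI weighting coefficient.
#' @return One-row data.frame with ndvi, savi, pri, wdrvi, swdrvi.
#' @export
vi_table <- function(rho531, rho570, rho670, rho850,
                     savi_L = 0.5, wdrvi_alpha = 0.2) {
  nd <- ndvi(rho850, rho670)
  wd <- wdrvi_from_ndvi(nd, wdrvi_alpha)
  data.frame(ndvi = nd,
             savi = savi(rho850, rho670, savi_L),
             pri = pri(rho570, rho531),
             wdrvi = wd,
             swdrvi = swdrvi(wd))
}
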