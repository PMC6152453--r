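# Vegetative/reproductive phase split, hysteresis slope tests and daily
# light-use efficiency.
#
# The hysteresis question: is the GEP_d-vs-VI slope during green-up
# (vegetative phase) different from the slope during grain filling and
# senescence (reproductive phase)? In dense winter cereals NDVI saturates
# early, so the vegetative-phase slope is steep while the reproductive
# slope is shallow; multiplying the VI by LAI restores a common slope.

#' Split one crop-year into vegetative and reproductive phases
#'
#' The split date defaults to the date of the seasonal LAI maximum
#' (rule "max_lai"); alternatives are the GEP_d maximum ("max_gep") or a
#' manual date. Records on the split date count as vegetative.
#'
#' @param daily One crop-year of daily records (doy, lai, gep_d).
#' @param rule `"max_lai"` (default), `"max_gep"` or `"manual"`.
#' @param split_doy Day of year for `rule = "manual"`.
#' @param min_records Minimum records required on each side; default 3.
#' @return List: split_doy, rule_used, vegetative and reproductive
#'   (logical index vectors into `daily`).
#' @export
split_phases <- function(daily, rule = c("max_lai", "max_gep", "manual"),
                         split_doy = NULL, min_records = 3) {
  rule <- match.arg(rule)
  sd <- switch(rule,
               max_lai = daily$doy[which.max(daily$lai)],
               max_gep = daily$doy[which.max(daily$gep_d)],
               manual = {
                 if (is.null(split_doy)) stop("manual rule needs split_doy")
                 split_doy
               })
  veg <- daily$doy <= sd
  if (sum(veg) < min_records || sum(!veg) < min_records)
    stop("fewer than ", min_records, " records in one phase (split doy ", sd, ")")
  list(split_doy = sd, rule_used = rule,
       vegetative = veg, reproductive = !veg)
}

#' Two-sample t-test on two regression slopes
#'
#' Welch-type test on the slope difference of two independently fitted
#' simple regressions: t = (a1 - a2) / sqrt(se1^2 + se2^2) with
#' Welch-Satterthwaite degrees of freedom built from each fit's residual
#' df (n - 2), two-sided p-value, and significance at `alpha`.
#'
#' @param fit1,fit2 Fits from [fit_gep_model()] (need slope, slope_se, n).
#' @param alpha Significance level; default 0.05.
#' @return Data.frame: slope1, slope2, se1, se2, t_stat, df, p_value,
#'   significant.
#' @export
slope_difference_test <- function(fit1, fit2, alpha = 0.05) {
  se1 <- fit1$slope_se; se2 <- fit2$slope_se
  pooled <- se1^2 + se2^2
  if (pooled == 0) stop("zero pooled standard error")
  t_stat <- (fit1$slope - fit2$slope) / sqrt(pooled)
  df1 <- fit1$n - 2; df2 <- fit2$n - 2
  df <- pooled^2 / (se1^4 / df1 + se2^4 / df2)
  p <- 2 * stats::pt(-abs(t_stat), df)
  data.frame(slope1 = fit1$slope, slope2 = fit2$slope,
             se1 = se1, se2 = se2, t_stat = t_stat, df = df,
             p_value = p, significant = p < alpha)
}

#' Phase-specific slope test for one crop-year and predictor
#'
#' Splits the crop-year, fits the same GEP_d model in each phase and
#' tests the slope difference.
#'
#' @param daily One crop-year of daily records.
#' @param model_id,vi_name Predictor specification as in
#'   [build_predictor()].
#' @param rule,split_doy Passed to [split_phases()].
#' @return One-row data.frame: the [slope_difference_test()] columns plus
#'   split_doy, n_veg, n_rep.
#' @export
phase_slope_test <- function(daily, model_id = 2, vi_name = "ndvi",
                             rule = "max_lai", split_doy = NULL) {
  sp <- split_phases(daily, rule = rule, split_doy = split_doy)
  x <- build_predictor(daily, model_id, if (model_id > 1) vi_name else NULL)
  f1 <- fit_gep_model(x[sp$vegetative], daily$gep_d[sp$vegetative], "vegetative")
  f2 <- fit_gep_model(x[sp$reproductive], daily$gep_d[sp$reproductive],
                      "reproductive")
  cbind(slope_difference_test(f1, f2),
        data.frame(split_doy = sp$split_doy,
                   n_veg = f1$n, n_rep = f2$n))
}

#' Daily light-use efficiency
#'
#' LUE = GEP_d / (PAR_d * daylength * 1e-6): grams of carbon fixed per
#' mol of incident photosynthetic photons over the daylight window.
#'
#' @param gep_d Daily GEP, gCO2-C m-2 d-1.
#' @param par_d Mean daylight PAR, umol m-2 s-1.
#' @param daylength_s Daylight duration, seconds.
#' @return LUE, gC per mol photons.
#' @export
lue_daily <- function(gep_d, par_d, daylength_s) {
  if (any(par_d <= 0)) stop("PAR_d must be positive")
  if (any(daylength_s <= 0)) stop("daylength must be positive")
  gep_d / (par_d * daylength_s * 1e-6)
}
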