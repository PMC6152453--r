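# Linear spectral models of daily GEP and their goodness-of-fit table.
#
# Four model families, all simple linear regressions of GEP_d:
#   model 1: GEP_d = a * LAI + b
#   model 2: GEP_d = a * VI + b
#   model 3: GEP_d = a * (VI * PAR_d) + b
#   model 4: GEP_d = a * (VI * LAI) + b
# RMSE uses divisor n and NRMSE is RMSE as a percentage of the observed
# GEP_d range, so printed RMSE/NRMSE pairs back-calculate to the range.

#' Build the predictor of one GEP_d model
#'
#' Records missing any required component (LAI for models 1 and 4, the VI
#' for models 2-4, PAR_d for model 3) yield NA and are dropped later by
#' pairwise deletion, which is why n differs between model rows.
#'
#' @param daily Daily records with columns gep_d, lai, par_d and VI columns.
#' @param model_id 1 (LAI), 2 (VI), 3 (VI*PAR_d) or 4 (VI*LAI).
#' @param vi_name VI column name for models 2-4 (e.g. "ndvi", "savi",
#'   "swdrvi", "pri"); ignored by model 1.
#' @return Numeric predictor vector (NA where a component is missing).
#' @export
build_predictor <- function(daily, model_id, vi_name = NULL) {
  stopifnot(model_id %in% 1:4)
  if (model_id == 1) return(daily$lai)
  if (is.null(vi_name) || !vi_name %in% names(daily))
    stop("models 2-4 need a VI column present in the daily table")
  vi <- daily[[vi_name]]
  switch(as.character(model_id),
         "2" = vi,
         "3" = vi * daily$par_d,
         "4" = vi * daily$lai)
}

#' Fit one linear GEP_d model
#'
#' Ordinary least squares of y on x with the goodness-of-fit statistics
#' used throughout: R2, RMSE (population form, divisor n), NRMSE =
#' 100 * RMSE / (max(y) - min(y)), and the two-sided p-value of the
#' slope t-test. Pairs with a missing component are dropped.
#'
#' @param x Predictor values.
#' @param y Observed GEP_d, gCO2-C m-2 d-1.
#' @param label Optional dataset label carried into the result.
#' @return One-row data.frame of class `gep_model_fit`: label, n, slope,
#'   intercept, slope_se, r2, rmse, nrmse, p_value.
#' @export
fit_gep_model <- function(x, y, label = "") {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs to fit")
  if (stats::var(x) == 0) stop("degenerate predictor: zero variance")
  fit <- stats::lm(y ~ x)
  res <- stats::residuals(fit)
  rmse <- sqrt(mean(res^2))
  rng <- diff(range(y))
  ss_res <- sum(res^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 0 else 1 - ss_res / ss_tot
  # closed-form slope inference (avoids summary.lm so exact synthetic
  # relations with zero residuals pass through cleanly)
  sxx <- sum((x - mean(x))^2)
  slope_se <- sqrt(ss_res / (n - 2) / sxx)
  slope <- unname(stats::coef(fit)[2])
  p <- if (slope_se == 0) 0 else
    2 * stats::pt(-abs(slope / slope_se), df = n - 2)
  out <- data.frame(
    label = label, n = n,
    slope = slope,
    intercept = unname(stats::coef(fit)[1]),
    slope_se = slope_se,
    r2 = r2, rmse = rmse,
    nrmse = if (rng > 0) 100 * rmse / rng else NA_real_,
    p_value = p,
    stringsAsFactors = FALSE)
  class(out) <- c("gep_model_fit", class(out))
  out
}

#' Goodness-of-fit table over crops, models and indices
#'
#' Fits every (group x model x VI) combination present in the data:
#' each crop separately, all cereals pooled, and all crops pooled.
#' Groups or combinations with too few complete pairs are skipped with
#' a message.
#'
#' @param daily Daily records: crop, gep_d, lai, par_d plus VI columns.
#' @param vi_names VI columns to sweep; default the four shipped indices.
#' @param cereals Crop labels pooled as "ALL cereals"; defaults to every
#'   crop whose name does not contain "potato".
#' @param pri_model2_only Restrict PRI to model 2 (no PRI products)?
#'   Default TRUE.
#' @return Data.frame: dataset, model_id, predictor plus the
#'   [fit_gep_model()] statistics columns.
#' @export
model_table <- function(daily, vi_names = c("ndvi", "savi", "swdrvi", "pri"),
                        cereals = NULL, pri_model2_only = TRUE) {
  if (is.null(cereals))
    cereals <- setdiff(unique(daily$crop),
                       grep("potato", unique(daily$crop),
                            ignore.case = TRUE, value = TRUE))
  groups <- c(
    stats::setNames(lapply(unique(daily$crop),
                           function(cr) daily[daily$crop == cr, ]),
                    unique(daily$crop)),
    list("ALL cereals" = daily[daily$crop %in% cereals, ],
         "cereals + potatoes" = daily))
  rows <- list()
  for (g in names(groups)) {
    dat <- groups[[g]]
    if (nrow(dat) == 0) { message("empty group skipped: ", g); next }
    specs <- rbind(
      data.frame(model_id = 1, vi = NA_character_),
      expand.grid(model_id = 2:4, vi = vi_names,
                  stringsAsFactors = FALSE))
    if (pri_model2_only)
      specs <- specs[!(specs$vi %in% "pri" & specs$model_id %in% 3:4), ]
    for (k in seq_len(nrow(specs))) {
      m <- specs$model_id[k]; vi <- specs$vi[k]
      x <- try(build_predictor(dat, m, if (m > 1) vi else NULL), silent = TRUE)
      if (inherits(x, "try-error")) next
      fit <- try(fit_gep_model(x, dat$gep_d, label = g), silent = TRUE)
      if (inherits(fit, "try-error")) {
        message("combination skipped (", g, ", model ", m, ", ", vi, ")")
        next
      }
      pred_name <- if (m == 1) "LAI" else
        paste0(toupper(vi), c("", "", "*PARd", "*LAI")[m])
      rows[[length(rows) + 1]] <-
        cbind(data.frame(dataset = g, model_id = m, predictor = pred_name,
                         stringsAsFactors = FALSE),
              fit[, setdiff(names(fit), "label")])
    }
  }
  do.call(rbind, rows)
}

#' Validate a general model crop by crop
#'
#' Applies a fitted general (pooled) model to each crop's records and
#' compares predicted with observed GEP_d: per-crop OLS of observed on
#' predicted, and the percentage bias 100 * (sum(pred) - sum(obs)) /
#' sum(obs). Crops whose |bias| exceeds `bias_limit` are flagged.
#'
#' @param general_fit A [fit_gep_model()] row (slope, intercept).
#' @param daily Per-crop daily records.
#' @param model_id,vi_name The predictor the general model was built on.
#' @param bias_limit Flag threshold on |bias_percent|, default 25.
#' @return Data.frame per crop: n, slope_obs_pred, intercept_obs_pred,
#'   r2, bias_percent, bias_flag.
#' @export
predict_and_validate <- function(general_fit, daily, model_id = 4,
                                 vi_name = "ndvi", bias_limit = 25) {
  rows <- lapply(unique(daily$crop), function(cr) {
    dat <- daily[daily$crop == cr, ]
    x <- build_predictor(dat, model_id, if (model_id > 1) vi_name else NULL)
    ok <- is.finite(x) & is.finite(dat$gep_d)
    if (sum(ok) < 3) stop("crop ", cr, ": too few records to validate")
    pred <- general_fit$slope * x[ok] + general_fit$intercept
    obs <- dat$gep_d[ok]
    if (sum(obs) <= 0) stop("crop ", cr, ": bias undefined for non-positive total")
    cmp <- stats::lm(obs ~ pred)
    bias <- 100 * (sum(pred) - sum(obs)) / sum(obs)
    ss_tot <- sum((obs - mean(obs))^2)
    r2 <- if (ss_tot == 0) 0 else
      1 - sum(stats::residuals(cmp)^2) / ss_tot
    data.frame(crop = cr, n = sum(ok),
               slope_obs_pred = unname(stats::coef(cmp)[2]),
               intercept_obs_pred = unname(stats::coef(cmp)[1]),
               r2 = r2,
               bias_percent = bias,
               bias_flag = abs(bias) > bias_limit,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
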