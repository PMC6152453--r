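# End-to-end orchestration: synthetic season -> closure fluxes -> campaign
# fits -> continuous reconstruction -> daily table -> spectral models ->
# validation -> phase tests. The same table contracts accept external
# (field) data through load_daily_table(), so synthetic and real runs are
# interchangeable.

#' Run the full chamber-to-spectral-model pipeline on a synthetic season
#'
#' Generates a season, processes every campaign's chamber closures
#' through the flux chain (slope fit, QC, Lloyd-Taylor and
#' Michaelis-Menten campaign fits), reconstructs the continuous 30-min
#' fluxes, aggregates estimated GEP_d per campaign day, merges with LAI
#' and vegetation indices, fits the spectral model table, validates the
#' pooled NDVI*LAI model per crop and runs the phase slope tests.
#'
#' @param config A [season_config()] (or list of them for a multi-crop
#'   run; seeds should differ between crops).
#' @param year Year label(s) for the daily table.
#' @param r2_min,near_zero_abs QC thresholds, see [qc_filter()].
#' @return List of class `gep_pipeline`: daily (merged table with
#'   estimated and true GEP_d), campaigns (fitted vs true parameters),
#'   fluxes30 (estimated), model_fits, validation, phase_tests, qc_log.
#' @export
run_season_pipeline <- function(config, year = 2011L, r2_min = 0.8,
                                near_zero_abs = 0.5) {
  configs <- if (inherits(config, "season_config")) list(config) else config
  years <- rep_len(year, length(configs))
  daily_all <- list(); camp_all <- list(); qc_all <- list(); flux30 <- list()
  for (ci in seq_along(configs)) {
    cfg <- configs[[ci]]
    season <- generate_season(cfg, year = years[ci])
    truth <- season$truth
    records <- do.call(rbind, lapply(season$closures, function(cl)
      do.call(rbind, lapply(cl, closure_flux))))
    records <- qc_filter(records, r2_min = r2_min,
                         near_zero_abs = near_zero_abs)
    records$doy <- as.integer(substr(records$closure_id, 2, 4))
    qc_all[[ci]] <- data.frame(
      crop = cfg$crop_label, n_closures = nrow(records),
      n_pass = sum(records$qc_flag == "pass"),
      n_excluded = sum(records$qc_flag == "excluded_r2"),
      n_near_zero = sum(records$qc_flag == "near_zero_review"))
    fit_one <- function(d) {
      day <- records[records$doy == d & records$qc_pass, ]
      out <- try(fit_campaign(day, d), silent = TRUE)
      if (inherits(out, "try-error")) {
        message("campaign doy ", d, " (", cfg$crop_label, ") unfittable")
        return(NULL)
      }
      out
    }
    campaigns <- do.call(rbind, lapply(unique(records$doy), fit_one))
    params30 <- interpolate_params(campaigns, truth$drivers$time)
    f30 <- reconstruct_30min(params30, truth$drivers)
    flux30[[ci]] <- cbind(crop = cfg$crop_label, f30)
    daily <- season$daily
    names(daily)[names(daily) == "gep_d"] <- "gep_d_true"
    daily$gep_d <- vapply(daily$doy, function(d)
      daily_gep(f30, d, day_window(d, cfg$latitude)), 0)
    daily_all[[ci]] <- daily
    camp_all[[ci]] <- cbind(crop = cfg$crop_label,
                            merge(campaigns, truth$params_true, by = "doy",
                                  suffixes = c("_fit", "_true")))
  }
  daily <- do.call(rbind, daily_all)
  fits <- model_table(daily)
  pooled <- fits[fits$dataset == "cereals + potatoes" &
                   fits$predictor == "NDVI*LAI", ]
  validation <- if (nrow(pooled) == 1)
    predict_and_validate(pooled, daily, model_id = 4, vi_name = "ndvi")
  else NULL
  phase <- do.call(rbind, lapply(unique(daily$crop), function(cr) {
    dat <- daily[daily$crop == cr, ]
    rbind(cbind(crop = cr, predictor = "NDVI",
                phase_slope_test(dat, model_id = 2, vi_name = "ndvi")),
          cbind(crop = cr, predictor = "NDVI*LAI",
                phase_slope_test(dat, model_id = 4, vi_name = "ndvi")))
  }))
  structure(list(daily = daily, campaigns = do.call(rbind, camp_all),
                 fluxes30 = do.call(rbind, flux30),
                 model_fits = fits, validation = validation,
                 phase_tests = phase, qc_log = do.call(rbind, qc_all)),
            class = "gep_pipeline")
}

#' Write the pipeline output tables as CSV
#'
#' @param pipeline A [run_season_pipeline()] result.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_pipeline_tables <- function(pipeline, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tabs <- Filter(is.data.frame, pipeline)
  paths <- vapply(names(tabs), function(nm) {
    p <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(tabs[[nm]], p, row.names = FALSE)
    p
  }, "")
  invisible(paths)
}

#' Load an external daily table
#'
#' Reads a delimited daily table (one row per plot x date) and maps its
#' columns onto the pipeline's daily-record contract via a column map,
#' so exported field datasets drop into [model_table()],
#' [predict_and_validate()] and [phase_slope_test()] unchanged. Rows
#' missing GEP_d are dropped with a message; rows missing LAI or a VI
#' are retained and excluded later only from the models that need them.
#'
#' @param path CSV path.
#' @param col_map Named character vector mapping contract names (crop,
#'   year, doy, gep_d, par_d, lai, ndvi, savi, swdrvi, pri) to the
#'   file's column names; identity for names omitted.
#' @param sep Field separator; default ",".
#' @return Data.frame of daily records.
#' @export
load_daily_table <- function(path, col_map = character(), sep = ",") {
  raw <- utils::read.csv(path, sep = sep, stringsAsFactors = FALSE)
  contract <- c("crop", "year", "doy", "gep_d", "par_d", "lai",
                "ndvi", "savi", "swdrvi", "pri")
  out <- list()
  for (nm in contract) {
    src <- if (nm %in% names(col_map)) col_map[[nm]] else nm
    out[[nm]] <- if (src %in% names(raw)) raw[[src]] else NA
  }
  out <- as.data.frame(out, stringsAsFactors = FALSE)
  if (all(is.na(out$gep_d))) stop("no mappable GEP_d column in ", path)
  drop <- !is.finite(suppressWarnings(as.numeric(out$gep_d)))
  if (any(drop))
    message(sum(drop), " rows without GEP_d dropped from ", basename(path))
  out[!drop, , drop = FALSE]
}
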