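# Study conditions shared by the numbered analysis scripts.
#
# Twelve synthetic crop-years (4 crops x 3 seasons) emulating a temperate
# lowland cropland experiment (52.43 N): two winter cereals that resume
# growth in spring with an already-dense canopy (so NDVI saturates early),
# a spring cereal sown in April, and an open-canopy potato planted in May.
# Seasonal LAI maxima follow the reported field values, with the dry
# first year expressed as reduced lai_max. Each crop-year has its own
# seed so weather and measurement noise differ between years.

library(cropgep)

study_configs <- function(base_seed = 100) {
  lai_max <- list(
    "winter wheat" = c(2.7, 3.3, 4.4),
    "winter rye" = c(2.9, 5.0, 4.3),
    "spring barley" = c(2.5, 4.0, 4.0),
    "potato" = c(1.8, 3.4, 3.2))
  peak <- list(
    "winter wheat" = c(126, 148, 148),
    "winter rye" = c(126, 146, 146),
    "spring barley" = c(148, 148, 165),
    "potato" = c(170, 170, 163))
  base <- list(
    "winter wheat" = list(start_doy = 65, end_doy = 215, lai_start = 1.0,
                          k_ext = 1.4),
    "winter rye" = list(start_doy = 65, end_doy = 210, lai_start = 1.4,
                        k_ext = 1.6),
    "spring barley" = list(start_doy = 105, end_doy = 230, lai_start = 0,
                           k_ext = 1.0),
    "potato" = list(start_doy = 130, end_doy = 255, lai_start = 0,
                    k_ext = 0.6, green_fraction_decline = 0.012))
  out <- list()
  i <- 0
  for (crop in names(base)) {
    for (y in 1:3) {
      i <- i + 1
      args <- c(list(crop_label = crop, lai_max = lai_max[[crop]][y],
                     lai_peak_doy = peak[[crop]][y],
                     seed = base_seed + i),
                base[[crop]])
      out[[i]] <- list(config = do.call(season_config, args),
                       year = 2010L + y)
    }
  }
  out
}

results_dir <- function() {
  d <- file.path("results")
  dir.create(d, showWarnings = FALSE, recursive = TRUE)
  d
}
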