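# Bundled reference values.

#' Reported seasonal maximum NDVI and sWDRVI per crop-year
#'
#' Seasonal maxima of NDVI and sWDRVI published for four crops (winter
#' wheat, winter rye, spring barley, potato) over three growing seasons
#' (2011-2013) of a long-term cropland field experiment in western
#' Poland, as printed (2 decimals). Used to check that the WDRVI/sWDRVI
#' transform chain reproduces the printed sWDRVI maxima from the printed
#' NDVI maxima.
#'
#' @return Data.frame: crop, year, ndvi_max, swdrvi_max.
#' @export
seasonal_max_vi <- function() {
  utils::read.csv(system.file("extdata", "crop_seasonal_max_vi.csv",
                              package = "cropgep"),
                  stringsAsFactors = FALSE)
}
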