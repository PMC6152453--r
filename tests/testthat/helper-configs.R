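# Compact season configurations keep the simulations fast while still
# covering the full phenology (green-up, peak, senescence).

quiet_config <- function(...) {
  season_config(conc_noise_ppm = 0, par_noise = 0, t_noise = 0,
                refl_noise = 0, ...)
}

short_config <- function(..., seed = 1) {
  season_config(start_doy = 90, end_doy = 160, lai_peak_doy = 125,
                campaign_interval_d = 10, seed = seed, ...)
}

# a single-campaign season for replicate parameter-recovery studies
one_campaign_config <- function(seed, ...) {
  season_config(start_doy = 80, end_doy = 120, lai_peak_doy = 100,
                campaign_interval_d = 50, seed = seed, ...)
}

# textbook normal-equation OLS, independent of lm()
ols_oracle <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  slope <- sum((x - mx) * (y - my)) / sum((x - mx)^2)
  intercept <- my - slope * mx
  res <- y - slope * x - intercept
  list(slope = slope, intercept = intercept,
       r2 = 1 - sum(res^2) / sum((y - my)^2),
       rmse = sqrt(mean(res^2)))
}
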