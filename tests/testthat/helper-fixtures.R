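# Shared fixtures: small grids, deterministic observers and quick sessions.

# On-grid observer: fixed true thresholds taken from the default contrast
# grid, slope on the default slope grid, lapse matching the QUEST+ grids.
on_grid_observer <- function(threshold_idx = c(`0` = 10, `90` = 9,
                                               `180` = 8, `270` = 9),
                             slope = 3, lapse = 0.02, ...) {
  m <- log(default_contrast_levels())[threshold_idx]
  names(m) <- names(threshold_idx)
  observer_model(m_fixed = m, true_slope = slope, lapse = lapse,
                 latency_contrast_gain_ms = 0, dir_noise_sd_deg = 2,
                 blink_rate = 0, ...)
}

# An observer that detects (essentially) everything, deterministically.
always_correct_observer <- function() {
  m <- rep(log(1e-9), 4)
  names(m) <- c("0", "90", "180", "270")
  observer_model(m_fixed = m, true_slope = 5.5, lapse = 0,
                 latency_contrast_gain_ms = 0, latency_sd_ms = 0,
                 dir_noise_sd_deg = 0, fp_rate = 0, blink_rate = 0)
}

# Exact (noise-free) rate table on a Weibull curve: fractional k = n * psi
# is legitimate under the binomial log-likelihood used by the fitter.
noise_free_rate_table <- function(p, contrasts = default_contrast_levels(),
                                  n = 1000) {
  data.frame(contrast = contrasts, n = n,
             k = n * weibull_prob(contrasts, p))
}

# Random binomial rate table from a known psychometric function.
sampled_rate_table <- function(p, contrasts = default_contrast_levels(),
                               n = 500) {
  data.frame(contrast = contrasts, n = n,
             k = stats::rbinom(length(contrasts), n,
                               weibull_prob(contrasts, p)))
}

small_geom <- function() screen_geometry(500, 400, pixels_per_degree = 40)
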