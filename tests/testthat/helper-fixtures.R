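# Shared fixtures, built in code.

default_plots <- function(seed = 1, ...) generate_plots(synthetic_config(seed = seed, ...))

# Noise-free generator configuration: identical loadings, no residual noise,
# so all four indicators are perfectly rank-correlated.
noisefree_config <- function(seed = 1) {
  synthetic_config(
    seed = seed,
    vigor_loadings = c(spad = 0.9, ph = 0.9, lai = 0.9, agb = 0.9),
    noise_sd = c(spad = 0, ph = 0, lai = 0, agb = 0),
    reflectance_params = {
      rp <- default_reflectance_params()
      rp$noise_sd[] <- 0
      rp
    })
}

# Bands of a single plausible plot, used for hand-computed index values.
bands1 <- c(b450 = 0.05, g550 = 0.11, r660 = 0.15, re750 = 0.25, nir840 = 0.45)
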