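# shared helpers: small grids and smooth random spectra built in code

default_grid <- function() spectral_grid()

# grid whose integration window covers all bands (no out-of-window tail)
window_grid <- function() spectral_grid(seq(400, 700, 10), c(400, 700))

# smooth random reflectances: sums of broad Gaussian bumps, clipped to [0, 1]
random_smooth_spectra <- function(n, grid = default_grid(), seed = 1) {
  wl <- grid$wavelengths
  vals <- savehsi:::.with_seed(seed, {
    t(replicate(n, {
      base <- runif(1, 0.05, 0.3)
      k <- sample(1:3, 1)
      bump <- rowSums(sapply(seq_len(k), function(i)
        runif(1, 0, 0.6) *
          exp(-((wl - runif(1, 420, 760))^2) / (2 * runif(1, 40, 90)^2))))
      pmin(pmax(base + bump, 0), 1)
    }))
  })
  attr(vals, "grid") <- grid
  vals
}

srgb_display_white <- function() linear_rgb_to_xyz(c(1, 1, 1))
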