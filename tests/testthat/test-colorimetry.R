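test_that("sRGB transfer functions decode, encode and round-trip exactly", {
  expect_equal(srgb_to_linear_rgb(0), 0)
  expect_equal(srgb_to_linear_rgb(1), 1)
  # closed form of the power branch
  expect_equal(srgb_to_linear_rgb(0.5), ((0.5 + 0.055) / 1.055)^2.4,
               tolerance = 1e-12)
  v <- seq(0, 1, length.out = 4097)
  expect_lt(max(abs(linear_rgb_to_srgb(srgb_to_linear_rgb(v)) - v)), 1e-12)
  expect_lt(max(abs(srgb_to_linear_rgb(linear_rgb_to_srgb(v)) - v)), 1e-12)
  expect_error(srgb_to_linear_rgb(1.2), "\\[0, 1\\]")
  expect_error(linear_rgb_to_srgb(-0.1), "\\[0, 1\\]")
})

test_that("linear RGB to XYZ uses the published sRGB/D65 primaries on the 0-100 scale", {
  expect_equal(unname(linear_rgb_to_xyz(c(0, 0, 0))), c(0, 0, 0))
  white <- linear_rgb_to_xyz(c(1, 1, 1))
  expect_equal(unname(white[2]), 100, tolerance = 1e-4)
  expect_equal(unname(white), c(95.0468, 100.0000, 108.883), tolerance = 1e-3)
  # red primary column, independent multiply against the published matrix
  expect_equal(unname(linear_rgb_to_xyz(c(1, 0, 0))),
               100 * c(0.4124564, 0.2126729, 0.0193339), tolerance = 1e-12)
  xyz <- matrix(runif(30, -10, 110), ncol = 3)
  expect_lt(max(abs(linear_rgb_to_xyz(xyz_to_linear_rgb(xyz)) - xyz)), 1e-9)
})

test_that("spectral integration is normalized so a perfect reflector has Y = 100", {
  g <- default_grid()
  cmf <- cmf_cie1931(g)
  white <- reflectance_spectrum(rep(1, n_bands(g)), g)
  for (illum in list(illuminant_d65(g), illuminant_equal_energy(g),
                     illuminant(seq(0.2, 2, length.out = n_bands(g)), g))) {
    expect_equal(unname(spectrum_to_xyz(white, illum, cmf)[2]), 100,
                 tolerance = 1e-9)
  }
  black <- reflectance_spectrum(rep(0, n_bands(g)), g)
  expect_equal(unname(spectrum_to_xyz(black, illuminant_d65(g), cmf)),
               c(0, 0, 0))
})

test_that("the white point matches an independent quadrature of the bundled tables", {
  g <- default_grid()
  cmf <- cmf_cie1931(g)
  d65 <- illuminant_d65(g)
  got <- d65_white_xyz(g)
  # brute-force trapezoid loop over the integration window
  wl <- g$wavelengths
  keep <- wl >= 400 & wl <= 700
  loop_trapz <- function(y) {
    x <- wl[keep]; y <- y[keep]
    s <- 0
    for (i in seq_len(length(x) - 1))
      s <- s + (x[i + 1] - x[i]) * (y[i] + y[i + 1]) / 2
    s
  }
  k <- 100 / loop_trapz(d65$power * cmf$ybar)
  oracle <- c(k * loop_trapz(d65$power * cmf$xbar),
              k * loop_trapz(d65$power * cmf$ybar),
              k * loop_trapz(d65$power * cmf$zbar))
  expect_equal(unname(got), oracle, tolerance = 1e-9)
  # and it is a plausible D65 white (within half a unit of the nominal one)
  expect_lt(max(abs(oracle - c(95.047, 100, 108.883))), 0.5)
})

test_that("tristimulus values scale linearly with reflectance", {
  g <- default_grid()
  cmf <- cmf_cie1931(g)
  d65 <- illuminant_d65(g)
  base <- random_smooth_spectra(1, g, seed = 3)[1, ]
  xyz1 <- spectrum_to_xyz(reflectance_spectrum(base, g), d65, cmf)
  for (c_ in c(0.15, 0.5, 0.99)) {
    xyz_c <- spectrum_to_xyz(reflectance_spectrum(c_ * base, g), d65, cmf)
    expect_equal(unname(xyz_c), unname(c_ * xyz1), tolerance = 1e-12)
  }
})

test_that("spectral integration rejects mismatched grids and a zero normalizer", {
  g <- default_grid()
  g2 <- spectral_grid(seq(400, 700, 10))
  cmf <- cmf_cie1931(g)
  r <- reflectance_spectrum(rep(0.5, n_bands(g)), g)
  expect_error(spectrum_to_xyz(r, illuminant_d65(g2), cmf), "grid")
  zero <- illuminant(rep(0, n_bands(g)), g)
  expect_error(spectrum_to_xyz(r, zero, cmf), "normalization")
})

test_that("the bundled observer has the expected luminous-efficiency peak", {
  g <- default_grid()
  cmf <- cmf_cie1931(g)
  expect_true(all(cmf$xbar >= 0 & cmf$ybar >= 0 & cmf$zbar >= 0))
  peak_wl <- g$wavelengths[which.max(cmf$ybar)]
  expect_lte(abs(peak_wl - 555), 10)
  expect_gt(max(cmf$ybar), 0.98 * 0.995)
})

test_that("Lab conversion honours its reference white and the L* closed form", {
  w <- d65_white_xyz()
  expect_equal(unname(xyz_to_lab(w, w)), c(100, 0, 0), tolerance = 1e-9)
  expect_equal(unname(xyz_to_lab(c(0, 0, 0), w)), c(0, 0, 0))
  grey <- w * 18.42 / 100
  lab <- xyz_to_lab(grey, w)
  expect_equal(unname(lab[1]), 116 * (18.42 / 100)^(1 / 3) - 16,
               tolerance = 1e-9)
  expect_lt(abs(lab[1] - 50), 0.1)
  expect_equal(unname(lab[2:3]), c(0, 0), tolerance = 1e-9)
  expect_error(xyz_to_lab(grey, c(95, -100, 108)), "positive")
})

test_that("CIEDE2000 reproduces the published verification pairs", {
  lab1 <- rbind(c(50, 2.6772, -79.7751), c(50, 3.1571, -77.2803),
                c(50, 2.8361, -74.0200), c(50, -1.3802, -84.2814),
                c(50, -1.1848, -84.8006), c(50, -0.9009, -85.5211),
                c(50, 0, 0), c(50, 2.49, -0.001))
  lab2 <- rbind(c(50, 0, -82.7485), c(50, 0, -82.7485), c(50, 0, -82.7485),
                c(50, 0, -82.7485), c(50, 0, -82.7485), c(50, 0, -82.7485),
                c(50, -1, 2), c(50, -2.49, 0.0009))
  expected <- c(2.0425, 2.8615, 3.4412, 1.0000, 1.0000, 1.0000,
                2.3669, 7.1792)
  expect_equal(ciede2000(lab1, lab2), expected, tolerance = 1e-4)
})

test_that("CIEDE2000 is symmetric, null on identity and positive otherwise", {
  set.seed(101)
  a <- cbind(runif(50, 0, 100), runif(50, -60, 60), runif(50, -60, 60))
  b <- a + matrix(runif(150, -20, 20), ncol = 3)
  expect_equal(ciede2000(a, b), ciede2000(b, a), tolerance = 1e-12)
  expect_equal(ciede2000(a, a), rep(0, 50))
  perturbed <- a
  perturbed[, 2] <- perturbed[, 2] + 1e-5
  expect_true(all(ciede2000(a, perturbed) > 0))
})

test_that("CIEDE2000 matches an independent reference implementation", {
  skip_if_not_installed("farver")
  set.seed(77)
  a <- cbind(runif(200, 0, 100), runif(200, -80, 80), runif(200, -80, 80))
  b <- cbind(runif(200, 0, 100), runif(200, -80, 80), runif(200, -80, 80))
  oracle <- diag(farver::compare_colour(a, b, from_space = "lab",
                                        method = "cie2000"))
  expect_equal(ciede2000(a, b), unname(oracle), tolerance = 1e-6)
})
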