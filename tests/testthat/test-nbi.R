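test_that("the band spectrum is a nonnegative weighted sum of Gaussian profiles", {
  g <- default_grid()
  m0 <- set_nbi_weights(nbi_model(), rep(0, 5))
  expect_equal(band_spectrum(m0, g)$power, rep(0, n_bands(g)))
  m1 <- nbi_model(list(nb415 = nbi_band(415, 30, 1),
                       nb540 = nbi_band(540, 30, 0)))
  s <- band_spectrum(m1, g)
  expect_equal(g$wavelengths[which.max(s$power)], 420 - 10) # nearest to 415
  m2 <- nbi_model(list(nb415 = nbi_band(415, 30, 1),
                       nb540 = nbi_band(540, 30, 1)))
  s2 <- band_spectrum(m2, g)
  expect_lt(s2$power[g$wavelengths == 780] / max(s2$power), 1e-6)
  broken <- m2; broken$bands <- list()
  expect_error(band_spectrum(broken, g), "empty")
})

test_that("NBI models validate their band list and display map", {
  expect_error(nbi_model(list(only_red = nbi_band(600, 20))), "415")
  expect_error(nbi_band(415, -5), "fwhm")
  expect_error(nbi_band(415, 30, 1.5), "weight")
  m <- nbi_model()
  expect_identical(m$display_map$nb415, c("G", "B"))
  expect_identical(m$display_map$nb540, "R")
  expect_error(nbi_model(m$bands, list(nb415 = "Q")), "display|entry")
})

test_that("the Cauchy-Lorentz density matches its closed forms and integrates to one", {
  expect_equal(cauchy_lorentz_pdf(0, 0, 1), 1 / pi, tolerance = 1e-12)
  expect_equal(cauchy_lorentz_pdf(3 + 2, 3, 2),
               cauchy_lorentz_pdf(3, 3, 2) / 2, tolerance = 1e-12)
  expect_equal(cauchy_lorentz_pdf(3 - 0.7, 3, 2), cauchy_lorentz_pdf(3 + 0.7, 3, 2))
  total <- stats::integrate(function(x) cauchy_lorentz_pdf(x, 1, 0.5),
                            1 - 1e4 * 0.5, 1 + 1e4 * 0.5)$value
  expect_equal(total, 1, tolerance = 1e-3)
  expect_error(cauchy_lorentz_pdf(0, 0, -1), "positive")
})

test_that("fast annealing honours its contract at zero iterations and finds a 1-D minimum", {
  cfg0 <- annealing_config(x0 = c(0.4, 0.6), bounds = c(0, 1), n_iter = 0)
  out <- fsa_minimize(function(x) sum(x^2), cfg0)
  expect_identical(out$par, c(0.4, 0.6))
  cfg <- annealing_config(x0 = 0, bounds = c(-10, 10), gamma = 1,
                          n_iter = 5000, seed = 11)
  fit <- fsa_minimize(function(x) (x - 2)^2, cfg)
  expect_lt(abs(fit$par - 2), 0.05)
  expect_error(fsa_minimize(function(x) NaN, cfg), "finite")
})

test_that("annealing is reproducible and its best-ever trace is monotone", {
  obj <- function(x) sum((x - c(0.2, 0.7, 0.5))^2) + 0.1 * sin(20 * x[1])
  cfg <- annealing_config(x0 = rep(0.5, 3), bounds = c(0, 1), n_iter = 800,
                          seed = 99)
  a <- fsa_minimize(obj, cfg)
  b <- fsa_minimize(obj, cfg)
  expect_identical(a$par, b$par)
  expect_identical(a$trace, b$trace)
  expect_true(all(diff(a$trace$best) <= 0))
  # doubling the budget under the same seed stream cannot end worse
  cfg2 <- annealing_config(x0 = rep(0.5, 3), bounds = c(0, 1), n_iter = 1600,
                           seed = 99)
  c_ <- fsa_minimize(obj, cfg2)
  expect_lte(c_$value, a$value)
  expect_equal(c_$trace$best[seq_len(800)], a$trace$best)
})

test_that("visiting steps follow the Cauchy distribution", {
  u <- savehsi:::.with_seed(123, stats::runif(1e5))
  steps <- tan(pi * (u - 0.5))
  ks <- suppressWarnings(stats::ks.test(steps, stats::pcauchy))
  expect_lt(unname(ks$statistic), 0.01)
})

test_that("annealing recovers planted NBI band weights", {
  g <- default_grid()
  checker <- colorchecker_reference(g)
  truth <- set_nbi_weights(nbi_model(), c(0.85, 0.65, 0.25, 0.4, 0.3))
  cols <- render_nbi_colors(checker, truth)
  ref_lab <- xyz_to_lab(linear_rgb_to_xyz(srgb_to_linear_rgb(cols)),
                        srgb_display_white())
  fit <- calibrate_nbi_weights(checker, ref_lab)
  expect_lt(fit$objective_value, 0.5)
  expect_true(all(nbi_weights(fit) >= 0 & nbi_weights(fit) <= 1))
  trace <- attr(fit, "trace")
  expect_true(all(diff(trace$best) <= 0))
  expect_error(calibrate_nbi_weights(checker, ref_lab[1:5, ]), "pair")
})

test_that("the display map routes band responses to the declared channels", {
  g <- default_grid()
  checker <- colorchecker_reference(g)
  only415 <- set_nbi_weights(nbi_model(), c(0.8, 0, 0, 0, 0))
  cols <- render_nbi_colors(checker, only415)
  expect_true(all(cols[, 1] == 0))          # red channel dark
  expect_true(all(cols[, 2] > 0))           # green and blue lit
  expect_identical(cols[, 2], cols[, 3])
})

test_that("the renderer is spatially faithful and linear before encoding", {
  g <- default_grid()
  m <- nbi_model()
  vals <- array(0.6, dim = c(4, 5, n_bands(g)))
  cube <- hyperspectral_cube(vals, g)
  img <- render_nbi_image(cube, m)
  flat <- matrix(img, ncol = 3)
  expect_lt(max(abs(sweep(flat, 2, flat[1, ]))), 1e-12)
  # linearity: scaling reflectance scales the pre-encoding intensities
  r <- random_smooth_spectra(6, g, seed = 71) * 0.5
  lin1 <- srgb_to_linear_rgb(render_nbi_colors(r, m, g))
  lin2 <- srgb_to_linear_rgb(render_nbi_colors(0.5 * r, m, g))
  expect_equal(lin2, 0.5 * lin1, tolerance = 1e-9)
})

test_that("a haemoglobin-like absorber separates from a flat reflector mostly in G and B", {
  g <- default_grid()
  wl <- g$wavelengths
  flat <- rep(0.8, length(wl))
  hb <- 0.8 - 0.7 * exp(-((wl - 415)^2) / (2 * 20^2)) -
    0.7 * exp(-((wl - 540)^2) / (2 * 25^2))
  spectra <- rbind(flat = flat, hb = pmin(pmax(hb, 0), 1))
  attr(spectra, "grid") <- g
  cols <- srgb_to_linear_rgb(render_nbi_colors(spectra, nbi_model(), g))
  d <- abs(cols[1, ] - cols[2, ])
  expect_gt(d[2] + d[3], d[1])
})

test_that("rendering rejects bands outside the cube grid", {
  g_short <- spectral_grid(seq(400, 700, 10), c(400, 700))
  cube <- hyperspectral_cube(array(0.5, c(2, 2, n_bands(g_short))), g_short)
  expect_error(render_nbi_image(cube, nbi_model()), "grid range")
})
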