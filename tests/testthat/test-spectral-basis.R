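test_that("an exactly low-rank spectra set is explained completely", {
  g <- default_grid()
  set.seed(11)
  base <- random_smooth_spectra(3, g, seed = 12)
  mix <- matrix(runif(30, 0, 0.4), ncol = 3)
  spectra <- 0.2 + mix %*% (base - 0.2)   # affine rank 3 about its mean
  attr(spectra, "grid") <- g
  b <- fit_spectral_basis(spectra, n_pc = 3)
  expect_equal(sum(b$explained_variance_ratio), 1, tolerance = 1e-10)
})

test_that("loadings are orthonormal, variance-ordered and sign-fixed", {
  b <- fit_spectral_basis(colorchecker_reference(), n_pc = 6)
  G <- b$loadings %*% t(b$loadings)
  expect_lt(max(abs(G - diag(6))), 1e-8)
  expect_true(all(diff(b$explained_variance_ratio) <= 1e-12))
  expect_lte(sum(b$explained_variance_ratio), 1 + 1e-12)
  for (j in seq_len(6)) {
    row <- b$loadings[j, ]
    expect_gt(row[which.max(abs(row))], 0)
  }
})

test_that("the SVD basis matches an independent covariance eigendecomposition", {
  spectra <- random_smooth_spectra(15, seed = 21)
  n_pc <- 4
  b <- fit_spectral_basis(spectra, n_pc = n_pc)
  # oracle: eigenvectors of the sample covariance matrix
  Xc <- sweep(spectra, 2, colMeans(spectra))
  eig <- eigen(stats::cov(spectra), symmetric = TRUE)
  Vo <- eig$vectors[, seq_len(n_pc)]
  recon_pkg <- sweep(b$scores %*% b$loadings, 2, -b$mean_spectrum)
  recon_orc <- sweep((Xc %*% Vo) %*% t(Vo), 2, -colMeans(spectra))
  expect_equal(sqrt(mean((spectra - recon_pkg)^2)),
               sqrt(mean((spectra - recon_orc)^2)), tolerance = 1e-8)
  # subspaces agree: projector difference vanishes
  P1 <- t(b$loadings) %*% b$loadings
  P2 <- Vo %*% t(Vo)
  expect_lt(max(abs(P1 - P2)), 1e-8)
})

test_that("basis fitting rejects impossible sizes", {
  spectra <- random_smooth_spectra(5, seed = 2)
  expect_error(fit_spectral_basis(spectra, n_pc = 5), "n_pc")
  expect_error(fit_spectral_basis(spectra[1:3, ], n_pc = 3, grid = default_grid()),
               "at least")
})

test_that("an order-1 identity alignment recovers the score embedding exactly", {
  spectra <- random_smooth_spectra(20, seed = 31)
  b <- fit_spectral_basis(spectra, n_pc = 3)
  tm <- fit_transformation_matrix(b, b$scores, feature_expansion(1))
  fitted <- expand_features(b$scores, tm$expansion) %*% t(tm$M)
  expect_lt(max(abs(fitted - b$scores)), 1e-8)
  expect_lt(tm$fit_rmse, 1e-10)
})

test_that("the transformation fit matches a brute-force least-squares oracle", {
  spectra <- random_smooth_spectra(30, seed = 41)
  b <- fit_spectral_basis(spectra, n_pc = 5)
  set.seed(42)
  xyz <- matrix(runif(90, 0, 5), ncol = 3)
  exp2 <- feature_expansion(2)
  tm <- fit_transformation_matrix(b, xyz, exp2)
  F_ <- expand_features(xyz, exp2)
  M_oracle <- t(solve(t(F_) %*% F_, t(F_) %*% b$scores))
  expect_equal(unname(tm$M), unname(M_oracle), tolerance = 1e-8)
  expect_error(fit_transformation_matrix(b, xyz[1:10, ]), "pair")
})

test_that("spectra in the basis span with consistent features reconstruct exactly", {
  spectra <- random_smooth_spectra(12, seed = 51)
  b <- fit_spectral_basis(spectra, n_pc = 3)
  # hand-built model whose order-1 features read the scores straight through
  M <- cbind(0, diag(3))
  tm <- structure(list(basis = b, expansion = feature_expansion(1), M = M,
                       score = b$scores, fit_rmse = 0),
                  class = "transformation_model")
  s <- c(0.02, -0.015, 0.01)
  target <- b$mean_spectrum + drop(s %*% b$loadings)
  got <- reconstruct_reflectance(tm, s, clip = FALSE)
  expect_lt(sqrt(mean((got$values - target)^2)), 1e-8)
})

test_that("training patches reconstruct within the fitted residual", {
  rt <- checker_roundtrip()
  checker <- colorchecker_reference()
  for (p in c("white", "black", "red", "cyan")) {
    expect_lt(spectral_rmse(rt$reconstructed[p, ], checker[p, ]),
              rt$max_rmse + 1e-9)
  }
})

test_that("clipping the reconstruction never hurts against in-range truth", {
  rt <- checker_roundtrip()
  tm <- rt$model$transformation
  corr <- rt$model$correction
  checker <- colorchecker_reference()
  cap <- simulate_capture(checker, synthetic_camera())
  xyz_c <- apply_correction(corr, linear_rgb_to_xyz(srgb_to_linear_rgb(cap$srgb)))
  raw <- reconstruct_reflectance(tm, xyz_c, clip = FALSE)
  clipped <- pmin(pmax(raw, 0), 1)
  rmse_raw <- sqrt(rowMeans((raw - checker)^2))
  rmse_clip <- sqrt(rowMeans((clipped - checker)^2))
  expect_true(all(rmse_clip <= rmse_raw + 1e-12))
})

test_that("the vectorized image chain equals the per-pixel loop", {
  rt <- checker_roundtrip()
  corr <- rt$model$correction
  tm <- rt$model$transformation
  set.seed(61)
  img <- array(runif(8 * 8 * 3), dim = c(8, 8, 3))
  cube <- rgb_image_to_cube(img, corr, tm)
  for (i in c(1, 5, 8)) for (j in c(2, 8)) {
    px <- img[i, j, ]
    sp <- reconstruct_reflectance(
      tm, apply_correction(corr, linear_rgb_to_xyz(srgb_to_linear_rgb(px))))
    expect_lt(max(abs(cube$values[i, j, ] - sp$values)), 1e-10)
  }
})

test_that("degenerate image inputs are rejected and uniform images stay uniform", {
  rt <- checker_roundtrip()
  corr <- rt$model$correction
  tm <- rt$model$transformation
  expect_error(rgb_image_to_cube(array(0, c(0, 4, 3)), corr, tm), "zero-size")
  expect_error(rgb_image_to_cube(matrix(0, 4, 4), corr, tm), "array")
  img <- array(rep(c(0.3, 0.6, 0.2), each = 9), dim = c(3, 3, 3))
  cube <- rgb_image_to_cube(img, corr, tm)
  flat <- matrix(cube$values, ncol = dim(cube$values)[3])
  expect_lt(max(abs(sweep(flat, 2, flat[1, ]))), 1e-12)
  # 1x1 image equals the direct single-colour chain
  one <- rgb_image_to_cube(array(c(0.3, 0.6, 0.2), c(1, 1, 3)), corr, tm)
  direct <- reconstruct_reflectance(
    tm, apply_correction(corr, linear_rgb_to_xyz(srgb_to_linear_rgb(c(0.3, 0.6, 0.2)))))
  expect_equal(drop(one$values), direct$values, tolerance = 1e-12)
})
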