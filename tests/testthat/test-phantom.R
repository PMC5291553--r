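test_that("Rician noise matches its analytic moments", {
  # sigma = 0 is the identity
  s <- c(0, 10, 500)
  expect_identical(add_rician_noise(s, sigma = 0), s)

  # S = 0: Rayleigh mean sigma * sqrt(pi/2)
  set.seed(3)
  draws <- add_rician_noise(rep(0, 2e4), sigma = 5, nex = 1)
  expect_equal(mean(draws), 5 * sqrt(pi / 2), tolerance = 0.02)
  expect_true(all(draws >= 0))

  # high SNR (S = 50 sigma): mean approaches sqrt(S^2 + sigma^2)
  S <- 50 * 5
  draws <- add_rician_noise(rep(S, 2e4), sigma = 5, nex = 1)
  expect_equal(mean(draws), sqrt(S^2 + 5^2), tolerance = 0.002)

  expect_error(add_rician_noise(-1, 1), "non-negative")
  expect_error(add_rician_noise(1, -1), "sigma")
  expect_error(add_rician_noise(1, 1, nex = 0), "nex")
})

test_that("NEX averaging shrinks variance like 1/nex at high SNR", {
  set.seed(5)
  S <- 1000; sigma <- 10
  v1 <- var(add_rician_noise(rep(S, 1e4), sigma, nex = 1))
  v4 <- var(add_rician_noise(rep(S, 1e4), sigma, nex = 4))
  expect_equal(v1 / v4, 4, tolerance = 0.15)
})

test_that("ellipsoid rasterisation matches the analytic volume", {
  ph <- generate_phantom(grid = c(48, 40, 32), radii = c(10, 8, 6),
                         snr = Inf, seed = 1)
  analytic <- 4 / 3 * pi * 10 * 8 * 6
  expect_lt(abs(sum(ph$lesion_mask) - analytic) / analytic, 0.05)
})

test_that("phantom generation is deterministic and validates geometry", {
  cfg <- list(grid = c(16, 16, 6), radii = c(5, 4, 2), snr = 20, seed = 9)
  p1 <- do.call(generate_phantom, cfg)
  p2 <- do.call(generate_phantom, cfg)
  expect_identical(p1$volume, p2$volume)
  expect_identical(p1$truth, p2$truth)
  expect_error(generate_phantom(grid = c(16, 16, 6), radii = c(9, 4, 2)),
               "fit inside")
  expect_error(generate_phantom(grid = c(16, 16, 6), radii = c(5, 4, 2),
                                snr = 0), "snr")
})

test_that("noiseless phantom volume equals the forward signal exactly", {
  ph <- generate_phantom(grid = c(12, 12, 4), radii = c(4, 4, 1.5),
                         snr = Inf, seed = 2)
  i <- which(ph$lesion_mask, arr.ind = TRUE)[1, ]
  p <- ivim_params(ph$truth$D[i[1], i[2], i[3]],
                   ph$truth$D_star[i[1], i[2], i[3]],
                   ph$truth$f[i[1], i[2], i[3]],
                   ph$truth$S0[i[1], i[2], i[3]])
  expect_equal(ph$volume[i[1], i[2], i[3], ], ivim_signal(p, ph$scheme),
               tolerance = 1e-12)
  expect_true(all(ph$volume >= 0))
})

test_that("voxel-wise fitting recovers a uniform noiseless phantom", {
  ph <- generate_phantom(grid = c(10, 10, 4), radii = c(3.5, 3.5, 1.5),
                         D_range = c(1.1e-3, 1.1e-3),
                         Dstar_range = c(20e-3, 20e-3),
                         f_range = c(0.25, 0.25),
                         snr = Inf, seed = 4)
  maps <- fit_parameter_maps(ph$volume, ph$scheme, ph$lesion_mask)
  vox <- tidy(maps)
  expect_true(all(vox$converged))
  expect_lt(max(abs(vox$D - 1.1e-3)) / 1.1e-3, 0.02)
  expect_lt(max(abs(vox$f - 0.25)) / 0.25, 0.02)
  expect_lt(max(abs(vox$D_star - 20e-3)) / 20e-3, 0.02)
  expect_lt(sd(vox$D), 1e-8)
  # out-of-mask voxels are missing
  expect_true(all(is.na(maps$D[!ph$lesion_mask])))
})

test_that("empty masks and shape mismatches are handled", {
  ph <- generate_phantom(grid = c(8, 8, 3), radii = c(2, 2, 1),
                         snr = Inf, seed = 6)
  empty <- array(FALSE, dim = dim(ph$lesion_mask))
  maps <- fit_parameter_maps(ph$volume, ph$scheme, empty)
  expect_identical(maps$n_attempted, 0L)
  expect_identical(maps$n_converged, 0L)
  expect_true(all(is.na(maps$D)))
  expect_error(
    fit_parameter_maps(ph$volume[, , , 1:5], ph$scheme, ph$lesion_mask),
    "4th axis"
  )
  expect_error(
    fit_parameter_maps(ph$volume, ph$scheme, empty[1:4, , ]),
    "spatial grid"
  )
})

test_that("lesion/background perfusion contrast survives noise", {
  ph <- generate_phantom(grid = c(14, 14, 4), radii = c(4, 4, 1.5),
                         snr = 50, seed = 8)
  mask <- array(TRUE, dim = dim(ph$lesion_mask))
  maps <- fit_parameter_maps(ph$volume, ph$scheme, mask)
  f_in <- mean(maps$f[ph$lesion_mask], na.rm = TRUE)
  f_out <- mean(maps$f[!ph$lesion_mask], na.rm = TRUE)
  expect_gt(f_in, f_out)
})
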