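make_uniform_maps <- function() {
  ph <- generate_phantom(grid = c(10, 10, 4), radii = c(3.5, 3.5, 1.5),
                         D_range = c(1.2e-3, 1.2e-3),
                         Dstar_range = c(18e-3, 18e-3),
                         f_range = c(0.3, 0.3),
                         snr = Inf, seed = 2)
  list(maps = fit_parameter_maps(ph$volume, ph$scheme, ph$lesion_mask),
       mask = ph$lesion_mask)
}

test_that("ROI summary returns the constant on homogeneous maps", {
  um <- make_uniform_maps()
  s <- roi_summary(um$maps, um$mask, seed = 1)
  # on a homogeneous map every re-draw averages the same constant: the
  # summary equals the (single) fitted voxel value exactly
  vox <- tidy(um$maps)
  expect_equal(s$D, vox$D[1], tolerance = 1e-12)
  expect_equal(s$f, vox$f[1], tolerance = 1e-12)
  expect_equal(s$D_star, vox$D_star[1], tolerance = 1e-12)
  # and that value is the phantom truth to fitting accuracy
  expect_equal(s$D, 1.2e-3, tolerance = 1e-3)
  expect_equal(s$f, 0.3, tolerance = 1e-2)
  expect_equal(s$D_star, 18e-3, tolerance = 2e-2)
  expect_identical(s$n_repeats, 3L)
  expect_error(roi_summary(um$maps, array(FALSE, dim = dim(um$mask))),
               "no fitted voxels")
})

test_that("ROI mean is the arithmetic mean and triplicates average", {
  um <- make_uniform_maps()
  maps <- um$maps
  # plant three known values in a 3-voxel ROI
  idx <- which(um$mask)[1:3]
  maps$D[idx] <- c(1, 2, 3) * 1e-3
  roi <- array(FALSE, dim = dim(maps$D)); roi[idx] <- TRUE
  s <- roi_summary(maps, roi, n_repeats = 1L, seed = 1)
  expect_equal(s$D, 2e-3)
  # mean of repeat means {2.0, 2.2, 1.8} is 2.0
  expect_equal(mean(c(2.0, 2.2, 1.8)), 2.0)
})

test_that("maximum transverse diameter matches brute-force pair scans", {
  vs <- c(2.5, 2.5, 6)
  # single voxel: 0 mm by convention
  m <- array(FALSE, dim = c(8, 8, 2)); m[4, 4, 1] <- TRUE
  expect_equal(max_diameter(m, vs), 0)
  # collinear 1 x n segment: (n-1) * pixel
  m <- array(FALSE, dim = c(10, 8, 2)); m[2:7, 3, 1] <- TRUE
  expect_equal(max_diameter(m, vs), 5 * 2.5)
  # rasterised disk of radius r: ~2 r * pixel, and equal to brute force
  r <- 5
  m <- array(FALSE, dim = c(16, 16, 3))
  for (i in 1:16) for (j in 1:16) {
    if ((i - 8)^2 + (j - 8)^2 <= r^2) m[i, j, 2] <- TRUE
  }
  got <- max_diameter(m, vs)
  idx <- which(m[, , 2], arr.ind = TRUE)
  pts <- cbind(idx[, 1] * vs[1], idx[, 2] * vs[2])
  brute <- max(stats::dist(pts))
  expect_equal(got, brute)
  expect_lt(abs(got - 2 * r * vs[1]), vs[1])
  expect_error(max_diameter(array(FALSE, c(2, 2, 2))), "empty")
})

test_that("lesion volume is voxel count x area x spacing and additive", {
  vs <- c(2.5, 2.5, 6)
  m <- array(FALSE, dim = c(10, 10, 4)); m[1:10, 1:10, 1] <- TRUE
  expect_equal(lesion_volume(m, vs), 100 * 2.5 * 2.5 * 6)
  m2 <- m; m2[1:10, 1:10, 3] <- TRUE
  expect_equal(lesion_volume(m2, vs), 2 * lesion_volume(m, vs))
  expect_warning(v0 <- lesion_volume(array(FALSE, c(2, 2, 2)), vs),
                 "empty")
  expect_equal(v0, 0)
})

test_that("delta computation reproduces the worked per-patient examples", {
  tbl <- tibble::tibble(
    id = c("responder", "non_responder"), pcr = c(TRUE, FALSE),
    D_pre = c(0.906, 1.110), D_mid = c(1.310, 1.410),
    Dstar_pre = c(40.4, 14.8), Dstar_mid = c(13.8, 27.4),
    f_pre = c(35.7, 29.2), f_mid = c(14.2, 21.4),
    MD_pre = c(40, 35), MD_mid = c(18, 30),
    V_pre = c(3e4, 2.5e4), V_mid = c(4e3, 1.8e4)
  )
  d <- compute_deltas(tbl)
  expect_equal(d$delta_D, c(-0.404, -0.300), tolerance = 1e-12)
  expect_equal(d$delta_f[2], 7.8, tolerance = 1e-12)
  expect_equal(d$delta_Dstar, c(26.6, -12.6), tolerance = 1e-12)
  expect_true(all(d$shrink_MD_pct <= 100 & d$shrink_V_pct <= 100))
  # identical timepoints give all-zero deltas
  same <- dplyr::mutate(tbl, D_mid = D_pre, Dstar_mid = Dstar_pre,
                        f_mid = f_pre, MD_mid = MD_pre, V_mid = V_pre)
  ds <- compute_deltas(same)
  expect_true(all(abs(c(ds$delta_D, ds$delta_f, ds$shrink_V_pct)) == 0))
  # a missing mid-treatment scan propagates NA deltas
  na_mid <- tbl; na_mid$D_mid[1] <- NA
  expect_true(is.na(compute_deltas(na_mid)$delta_D[1]))
  expect_error(compute_deltas(tbl[, 1:4]), "missing columns")
})

test_that("cutoff classification puts both worked examples on the pCR side", {
  d <- c(responder = -0.404, non_responder = -0.300)
  pred <- classify_by_cutoff(d, -0.163, "<=")
  expect_true(all(pred))  # the non-responder is a false positive
  # tie lands on the positive side, either direction
  expect_true(classify_by_cutoff(-0.163, -0.163, "<="))
  expect_true(classify_by_cutoff(-0.163, -0.163, ">="))
  expect_false(classify_by_cutoff(-0.05, -0.163, "<="))
})
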