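test_that("cylinder stacking and z-extension count voxels correctly", {
  m <- disc_mask(21, 5.5)
  area <- sum(m)
  cyl <- stack_cylinder(m, 1:21)
  expect_equal(sum(cyl), area * 21)
  expect_equal(stack_cylinder(m, 4, n_z = 10)[, , 4], m, ignore_attr = TRUE)
  expect_error(stack_cylinder(matrix(0L, 5, 5), 1:3), class = "empty_mask")
  ext <- extend_mask_z(m, central_z = 15, n_z = 40)
  expect_equal(attr(ext, "z_range"), c(5L, 25L))  # 21 slices
  expect_false(attr(ext, "clipped"))
  expect_equal(sum(apply(ext, 3, sum) > 0), 21L)
  clip <- extend_mask_z(m, central_z = 3, n_z = 40)
  expect_equal(attr(clip, "z_range"), c(1L, 13L))
  expect_true(attr(clip, "clipped"))
  one <- extend_mask_z(m, central_z = 7, n_z = 40, n_slices = 0)
  expect_equal(sum(apply(one, 3, sum) > 0), 1L)
})

test_that("spot detection finds blobs and survives degenerate input", {
  d <- c(40, 40, 24)
  one <- gaussian_blob(d, c(20, 20, 12), c(3, 3, 2), A = 300, B = 5)
  seg <- detect_spots(one, array(1L, d), method = "yen")
  expect_length(seg$voxel_counts, 1L)
  two <- one + gaussian_blob(d, c(10, 30, 8), c(3, 3, 2), A = 300, B = 0)
  two <- two + gaussian_blob(d, c(30, 10, 16), c(3, 3, 2), A = 300, B = 0) -
    gaussian_blob(d, c(20, 20, 12), c(3, 3, 2), A = 300, B = 0)
  seg2 <- detect_spots(two, array(1L, d), method = "yen")
  expect_length(seg2$voxel_counts, 2L)
  expect_lt(abs(diff(seg2$voxel_counts)) / max(seg2$voxel_counts), 0.1)
  expect_warning(empty <- detect_spots(array(3, d), array(1L, d)),
                 "no foreground")
  expect_length(empty$voxel_counts, 0L)
  expect_error(detect_spots(one, array(0L, d)), class = "empty_mask")
})

test_that("nucleolus selection follows annotation then overlap", {
  d <- c(40, 40, 24)
  two <- gaussian_blob(d, c(12, 12, 12), c(3, 3, 2), A = 300) +
    gaussian_blob(d, c(30, 30, 12), c(2, 2, 1.5), A = 300)
  seg <- detect_spots(two, array(1L, d), method = "yen")
  expect_length(seg$voxel_counts, 2L)
  picked <- select_nucleolus(seg, annotation = c(30, 30, 12))
  expect_equal(picked[30, 30, 12], 1L)
  expect_equal(attr(picked, "rule"), "annotation")
  # annotation in background: larger label overlapping the nucleus wins
  nucleus <- array(1L, d)
  picked2 <- select_nucleolus(seg, annotation = c(1, 1, 1),
                              nucleus_mask = nucleus)
  expect_equal(attr(picked2, "rule"), "largest_overlap")
  expect_equal(sum(picked2), max(seg$voxel_counts))
  outside <- array(0L, d); outside[1:2, 1:2, 1:2] <- 1L
  expect_error(select_nucleolus(seg, annotation = c(1, 1, 1),
                                nucleus_mask = outside),
               class = "label_not_found")
})

test_that("3D Gaussian fit recovers sigmas, volume and units", {
  d <- c(41, 41, 61)
  sig <- c(3, 3, 5)
  g <- gaussian_blob(d, c(21, 21, 31), sig, A = 500)
  seg <- detect_spots(g, array(1L, d), method = "yen")
  fit <- fit_gaussian3d(g, seg$labels == 1)
  expect_true(fit$converged)
  s_hat <- coef(fit)[c("sigma_y", "sigma_x", "sigma_z")]
  expect_true(all(abs(s_hat / sig - 1) < 0.02))
  v_true <- 4 / 3 * pi * prod(sig)
  expect_lt(abs(fit$volume_vox / v_true - 1), 0.06)
  # unit sigma closed form
  u <- gaussian_blob(c(15, 15, 15), c(8, 8, 8), c(1, 1, 1), A = 100)
  fu <- fit_gaussian3d(u, array(1L, c(15, 15, 15)))
  expect_equal(fu$volume_vox, 4 * pi / 3, tolerance = 1e-7)
  # anisotropic pitch: um^3 = voxel^3 x (0.1 * 0.1 * 0.2)
  fa <- fit_gaussian3d(g, seg$labels == 1, voxel_xy = 0.1, voxel_z = 0.2)
  expect_equal(fa$volume_um3, fa$volume_vox * 0.002)
  small <- array(0L, d); small[21, 21, 31] <- 1L
  expect_error(fit_gaussian3d(g, small), class = "too_few_voxels")
})

test_that("volume is invariant to the detection smoothing sigma", {
  d <- c(41, 41, 41)
  g <- gaussian_blob(d, c(21, 21, 21), c(3.5, 3, 4), A = 400)
  vols <- vapply(c(0.5, 0.75, 1.5), function(ss) {
    seg <- detect_spots(g, array(1L, d), smoothing_sigma = ss,
                        method = "auto")
    fit_gaussian3d(g, seg$labels == 1)$volume_vox
  }, numeric(1))
  expect_lt(max(abs(vols / vols[2] - 1)), 0.01)
})

test_that("relative volumes and the rank-sum comparison behave", {
  set.seed(8)
  control <- exp(rnorm(30, log(3), 0.25))
  same <- relative_volume(control, control)
  expect_equal(same$median_ratio, 1)
  expect_gt(same$p_value, 0.9)
  half <- relative_volume(control * 0.5, control)
  expect_equal(half$median_ratio, 0.5)
  treated <- exp(rnorm(30, log(3 * 0.4), 0.25))
  rv <- relative_volume(treated, control)
  expect_lt(rv$p_value, 0.01)
  expect_lt(abs(rv$median_ratio / 0.4 - 1), 0.15)
  expect_error(relative_volume(control, rep(0, 5)), class = "invalid_input")
})

test_that("FISH quantification is exactly background-corrected", {
  d <- c(30, 30, 15)
  const <- array(11, d)
  lab <- array(0L, d); lab[10:15, 10:15, 6:9] <- 1L
  nucleus <- array(1L, d)
  fq <- integrated_fish_signal(const, lab, nucleus, central_z = 8)
  expect_equal(fq$corrected_sum, 0)
  # invariance to a constant offset
  spot <- const + gaussian_blob(d, c(12, 12, 7), c(2, 2, 1.5), A = 200)
  f1 <- integrated_fish_signal(spot, lab, nucleus, central_z = 8)
  f2 <- integrated_fish_signal(spot + 50, lab, nucleus, central_z = 8)
  expect_equal(f1$corrected_sum, f2$corrected_sum, tolerance = 1e-9)
  # empty segmentation: zero sum, zero voxels
  f0 <- integrated_fish_signal(spot, array(0L, d), nucleus, central_z = 8)
  expect_equal(f0$corrected_sum, 0)
  expect_equal(f0$n_voxels, 0L)
  full <- array(1L, d)
  expect_error(integrated_fish_signal(spot, full, nucleus, central_z = 8),
               class = "no_background")
})

test_that("projected areas follow the stated geometry", {
  base <- disc_mask(31, 5.6)
  cyl <- stack_cylinder(base, 3:12, n_z = 15)
  out <- nucleolar_nuclear_area(cyl, disc_mask(31, 12), voxel_xy = 0.13)
  expect_equal(out$nucleolus_area, sum(base) * 0.13^2)
  # sphere projects to a disc of the same radius
  r <- 8
  sph <- array(0L, c(25, 25, 21))
  for (k in 1:21) {
    r2 <- r^2 - (k - 11)^2
    if (r2 > 0) sph[, , k] <- disc_mask(25, sqrt(r2))
  }
  out2 <- nucleolar_nuclear_area(sph, disc_mask(25, 10))
  expect_lt(abs(out2$nucleolus_area / (pi * r^2) - 1), 0.05)
  # nucleolus mask equal to nucleus mask gives ratio 1
  m <- disc_mask(21, 6)
  out3 <- nucleolar_nuclear_area(stack_cylinder(m, 1:5), m)
  expect_equal(out3$ratio, 1)
  expect_error(nucleolar_nuclear_area(array(0L, c(5, 5, 5)), m),
               class = "empty_mask")
})

test_that("detection plus fit recovers imaged nucleolar volumes", {
  set.seed(30)
  rel_err <- vapply(1:12, function(i) {
    s <- runif(3, 0.45, 0.75)
    cfg <- scene_config(nucleolus_sigmas = s, seed = 3000 + i)
    sc <- generate_nucleus_scene(cfg)
    seg <- detect_spots(sc$channels$nucleolus, sc$mask3d, method = "auto")
    nm <- select_nucleolus(seg, annotation = sc$nucleolus_center,
                           nucleus_mask = sc$mask3d)
    fit <- fit_gaussian3d(sc$channels$nucleolus, nm, sc$voxel_xy, sc$voxel_z)
    # centroid of the selected label close to the true centre
    idx <- arrayInd(which(nm > 0), dim(nm))
    expect_lt(max(abs(colMeans(idx) - sc$nucleolus_center)), 1.5)
    fit$volume_vox / sc$truth$nucleolus_volume_eff_vox - 1
  }, numeric(1))
  expect_lt(median(abs(rel_err)), 0.1)
})
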