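test_that("contours are ordered boundaries of single components", {
  sq <- matrix(0L, 9, 9); sq[4:6, 4:6] <- 1L
  ct <- extract_contour(sq)
  expect_equal(nrow(ct), 8L)  # the 8 perimeter pixels of a 3x3 square
  expect_setequal(paste(ct[, 1], ct[, 2]),
                  setdiff(paste(rep(4:6, each = 3), rep(4:6, 3)), "5 5"))
  # disc of radius 20: polygon length close to the circumference
  # (8-connected pixel-centre polygons carry a ~5% positive bias)
  dm <- disc_mask(51, 20)
  ct <- extract_contour(dm)
  per <- sum(sqrt(rowSums((ct - ct[c(2:nrow(ct), 1), ])^2)))
  expect_lt(abs(per - 2 * pi * 20) / (2 * pi * 20), 0.06)
  two <- matrix(0L, 9, 9); two[2, 2] <- 1L; two[8, 8] <- 1L
  expect_error(extract_contour(two), class = "multi_component_mask")
  expect_error(extract_contour(matrix(0L, 5, 5)), class = "empty_mask")
})

test_that("ray sampling is exact on constant and linear fields", {
  dm <- disc_mask(41, 15)
  ct <- extract_contour(dm)
  const <- matrix(7, 41, 41)
  rays <- sample_rays(const, c(21, 21), ct)
  expect_true(all(rays$samples$intensity == 7))
  expect_equal(length(rays$lengths), nrow(ct))
  # circular contour: all ray lengths equal the radius within a pixel
  expect_true(all(abs(rays$lengths - 15) <= 1))
  expect_true(all(tapply(rays$samples$dist, rays$samples$ray,
                         function(d) all(diff(d) > 0))))
  # final sample exactly at the contour point
  last_d <- tapply(rays$samples$dist, rays$samples$ray, max)
  expect_equal(as.numeric(last_d), unname(rays$lengths))
  # bilinear sampling of a linear field is exact: f = 2 + 0.3 y + 0.7 x
  lin <- outer(1:41, 1:41, function(y, x) 2 + 0.3 * y + 0.7 * x)
  rays <- sample_rays(lin, c(21, 21), ct)
  i <- sample(nrow(rays$samples), 10)
  s <- rays$samples[i, ]
  frac <- s$dist / rays$lengths[s$ray]
  yy <- 21 + (ct[s$ray, 1] - 21) * frac
  xx <- 21 + (ct[s$ray, 2] - 21) * frac
  expect_equal(s$intensity, 2 + 0.3 * yy + 0.7 * xx, tolerance = 1e-12)
  expect_error(sample_rays(const, c(1, 1), ct),
               class = "center_outside_contour")
})

test_that("binning matches a brute-force per-sample loop", {
  set.seed(21)
  dists <- lapply(1:5, function(i) sort(runif(200, 0, 10)))
  ints <- lapply(1:5, function(i) runif(200))
  rays <- make_rays(dists, ints, lengths = rep(10, 5))
  prof <- bin_and_normalize(rays)
  # oracle: explicit per-sample assignment to half-open bins
  rel <- unlist(dists) / 10
  val <- unlist(ints)
  oracle <- numeric(20); cnt <- integer(20)
  for (j in seq_along(rel)) {
    b <- min(floor(rel[j] / 0.05) + 1, 20)
    oracle[b] <- oracle[b] + val[j]; cnt[b] <- cnt[b] + 1L
  }
  oracle <- oracle / cnt
  expect_equal(prof$intensity, oracle / max(oracle))
  expect_equal(prof$n_samples, cnt)
  expect_equal(sum(prof$n_samples), length(rel))  # exhaustive and exclusive
  # a single sample at distance 0 contributes to the 2.5% bin
  one <- make_rays(list(0), list(5), lengths = 3)
  p1 <- suppressWarnings(bin_and_normalize(one))
  expect_equal(p1$n_samples[1], 1L)
  expect_true(all(p1$n_samples[-1] == 0L))
  expect_true(all(p1$interpolated[-1]))
  expect_error(bin_and_normalize(make_rays(list(0), list(1), lengths = 0)),
               class = "zero_length_ray")
})

test_that("constant-intensity rays give a flat unit profile", {
  rays <- make_rays(lapply(1:8, function(i) seq(0, 12, 0.5)),
                    lapply(1:8, function(i) rep(3.5, 25)),
                    lengths = rep(12, 8))
  prof <- bin_and_normalize(rays)
  expect_equal(prof$intensity, rep(1, 20))
  expect_true(prof$normalized)
  # all-zero intensities: normalization skipped with a warning
  z <- make_rays(list(seq(0, 10, 0.5)), list(rep(0, 21)), lengths = 10)
  expect_warning(pz <- bin_and_normalize(z), "max-normalization skipped")
  expect_false(pz$normalized)
})

test_that("per-ray and pooled binning agree on balanced sampling", {
  rays <- make_rays(lapply(1:6, function(i) seq(0, 10, 0.25)),
                    lapply(1:6, function(i) runif(41)),
                    lengths = rep(10, 6))
  a <- bin_and_normalize(rays, method = "pooled")
  b <- bin_and_normalize(rays, method = "per_ray")
  expect_equal(a$intensity, b$intensity, tolerance = 1e-12)
})

test_that("condition profiles average with a normal-approximation band", {
  base <- structure(list(centers = seq(2.5, 97.5, 5),
                         intensity = seq(0.05, 1, 0.05),
                         n_samples = rep(5L, 20), normalized = TRUE,
                         interpolated = rep(FALSE, 20), nucleus_id = "a"),
                    class = "binned_profile")
  same <- condition_profile(list(base, base, base))
  expect_equal(same$mean, base$intensity)
  expect_equal(same$half_width, rep(0, 20))
  expect_warning(single <- condition_profile(list(base)), "single profile")
  expect_equal(single$half_width, rep(0, 20))
  set.seed(3)
  profs <- lapply(1:20, function(i) {
    p <- base; p$intensity <- runif(20); p
  })
  cp <- condition_profile(profs)
  mat <- do.call(rbind, lapply(profs, function(p) p$intensity))
  expect_equal(cp$mean, colMeans(mat))
  expect_equal(cp$half_width,
               qnorm(0.975) * apply(mat, 2, sd) / sqrt(20))
  bad <- profs; bad[[1]]$normalized <- FALSE
  expect_error(condition_profile(bad), class = "mixed_normalization")
})

test_that("resolvability filter keeps exactly the long rays", {
  lens <- c(25, 14, 9.4, 30, 10)
  edge <- c(5, 6, 1, 21.5, 0.5)
  rays <- make_rays(lapply(lens, function(L) seq(0, L, 0.5)),
                    lapply(lens, function(L) runif(length(seq(0, L, 0.5)))),
                    lengths = lens, edge = edge)
  keep_oracle <- which(lens - edge >= 9)  # brute-force length check
  out <- filter_resolvable_rays(rays, 9)
  expect_equal(length(out$lengths), length(keep_oracle))
  expect_equal(out$lengths, lens[keep_oracle])
  expect_equal(attr(out, "discarded"), length(lens) - length(keep_oracle))
  expect_warning(filter_resolvable_rays(rays, 50), "no rays pass")
  no_edge <- make_rays(list(0:5), list(rep(1, 6)), lengths = 5)
  expect_error(filter_resolvable_rays(no_edge, 9),
               class = "missing_edge_crossing")
})

test_that("edge profiles are anchored at the nucleolus edge", {
  # circular nucleolus of radius 1 um (10 px at 0.1 um/px): a sample at
  # 1.5 um from the centre lies 0.5 um beyond the edge
  n <- 61; ctr <- 31
  nucleolus <- disc_mask(n, 10)
  plane <- matrix(1, n, n)
  contour <- extract_contour(disc_mask(n, 28))
  rays <- sample_rays(plane, c(ctr, ctr), contour,
                      nucleolus_mask = nucleolus)
  ep <- nucleolus_edge_profile(rays, voxel_xy = 0.1)
  # 15 px from centre = 1.5 um: edge distance 0.5 um -> third 0.25-um bin
  samp <- rays$samples[1, ]
  edge_um <- rays$edge_crossing[1] * 0.1
  expect_equal(edge_um, 1.0, tolerance = 0.1)
  expect_equal((15 - rays$edge_crossing[1]) * 0.1, 0.5, tolerance = 0.1)
  # fasted scene: profile maximum in the first bin beyond the edge;
  # fed scene: first bin well below the global maximum
  for (mode in c("fasted", "fed")) {
    cfg <- scene_config(chromatin_mode = mode, photon_scale = Inf,
                        read_noise_sd = 0)
    sc <- generate_nucleus_scene(cfg)
    plane <- sc$channels$chromatin[, , sc$central_z]
    nm <- nucleolus_truth_mask(sc)[, , sc$central_z]
    rays <- sample_rays(plane, sc$nucleolus_center[c("y", "x")],
                        extract_contour(sc$mask2d), nucleolus_mask = nm)
    ep <- nucleolus_edge_profile(rays, voxel_xy = sc$voxel_xy)
    if (mode == "fasted") {
      expect_equal(which.max(ep$intensity), 1L)
    } else {
      expect_lt(ep$intensity[1], 0.8 * max(ep$intensity, na.rm = TRUE))
    }
  }
})

test_that("2D and 3D segmentation give matching profiles on noiseless scenes", {
  cfg <- scene_config(chromatin_mode = "fasted", photon_scale = Inf,
                      read_noise_sd = 0)
  sc <- generate_nucleus_scene(cfg)
  p2d <- profile_scene(sc, use_3d_mask = FALSE)
  p3d <- profile_scene(sc, use_3d_mask = TRUE)
  expect_lt(max(abs(p2d$intensity - p3d$intensity) /
                  pmax(abs(p2d$intensity), 1e-9)), 0.01)
})
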