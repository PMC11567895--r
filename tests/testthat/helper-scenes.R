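# Shared fixtures, all generated in code.

# Small, fast scene configuration (muscle-sized nucleus) for tests that
# need many scenes.
tiny_config <- function(...) {
  scene_config(tissue = "muscle", nucleolus_sigmas = c(0.35, 0.35, 0.35),
               ...)
}

# Filled disc mask of radius r centred in an n x n matrix.
disc_mask <- function(n, r, cy = (n + 1) / 2, cx = (n + 1) / 2) {
  m <- matrix(0L, n, n)
  for (y in 1:n) for (x in 1:n)
    if ((y - cy)^2 + (x - cx)^2 <= r^2) m[y, x] <- 1L
  m
}

# Separable 3D Gaussian blob (+ offset) on a given grid.
gaussian_blob <- function(d, ctr, sig, A = 100, B = 0) {
  g <- array(0, d)
  for (k in seq_len(d[3])) {
    g[, , k] <- B + A *
      exp(-outer((seq_len(d[1]) - ctr[1])^2 / (2 * sig[1]^2),
                 (seq_len(d[2]) - ctr[2])^2 / (2 * sig[2]^2), "+")) *
      exp(-(k - ctr[3])^2 / (2 * sig[3]^2))
  }
  g
}

# Rotate a (y, x, z) stack by 90 degrees in the xy plane.
rotate90_stack <- function(a) {
  d <- dim(a)
  out <- array(0, c(d[2], d[1], d[3]))
  for (k in seq_len(d[3])) out[, , k] <- t(a[, , k])[, d[1]:1, drop = FALSE]
  out
}

# Build a radial_rays object directly (unit-tested container shape).
make_rays <- function(dists, intensities, lengths, edge = NULL) {
  ray <- rep(seq_along(dists), lengths(dists))
  structure(list(samples = data.frame(ray = ray,
                                      dist = unlist(dists),
                                      intensity = unlist(intensities)),
                 lengths = lengths, edge_crossing = edge,
                 center = c(0, 0), step = 0.5),
            class = "radial_rays")
}
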