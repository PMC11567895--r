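# Internal numerical helpers shared across modules.

#' Evaluate an expression with a locally seeded RNG
#'
#' Saves and restores `.Random.seed` so that seeded generators do not
#' disturb the caller's RNG stream. `seed = NULL` leaves the stream alone.
#' @noRd
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' 1D Gaussian kernel, truncated at 4 sigma and normalized to sum 1
#' @noRd
gaussian_kernel_1d <- function(sigma, truncate = 4) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(truncate * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

# Convolve a 3D array along one dimension with a 1D kernel, replicating
# edge values (nearest-neighbour padding, as standard image filters do).
convolve_along <- function(a, kernel, dim_index) {
  if (length(kernel) == 1L) return(a)
  d <- dim(a)
  perm <- c(dim_index, setdiff(seq_along(d), dim_index))
  ap <- aperm(a, perm)
  n <- dim(ap)[1L]
  m <- matrix(ap, nrow = n)
  r <- (length(kernel) - 1L) / 2L
  idx <- c(rep(1L, r), seq_len(n), rep(n, r))
  padded <- m[idx, , drop = FALSE]
  out <- matrix(0, nrow = n, ncol = ncol(m))
  for (j in seq_along(kernel)) {
    out <- out + kernel[j] * padded[(j - 1L) + seq_len(n), , drop = FALSE]
  }
  res <- array(out, dim = dim(ap))
  aperm(res, order(perm))
}

#' Separable anisotropic Gaussian filter for 3D stacks
#'
#' Smooths a `(y, x, z)` array with a Gaussian of per-axis standard
#' deviation `sigma` (voxels), using separable 1D convolutions with
#' edge replication. A sigma of 0 skips that axis.
#'
#' @param a 3D numeric array `(y, x, z)` (a 2D matrix is treated as a
#'   single-slice stack).
#' @param sigma numeric length-3 vector `(sigma_y, sigma_x, sigma_z)` in
#'   voxels, or a scalar applied isotropically.
#' @return Smoothed array of the same dimensions.
#' @export
gaussian_blur_3d <- function(a, sigma) {
  was_matrix <- is.matrix(a)
  if (was_matrix) a <- array(a, dim = c(dim(a), 1L))
  stopifnot(length(dim(a)) == 3L)
  if (length(sigma) == 1L) sigma <- rep(sigma, 3L)
  stopifnot(length(sigma) == 3L, all(sigma >= 0))
  for (k in 1:3) {
    if (sigma[k] > 0) a <- convolve_along(a, gaussian_kernel_1d(sigma[k]), k)
  }
  if (was_matrix) a <- a[, , 1L]
  a
}

#' Bilinear interpolation of a 2D image at continuous coordinates
#'
#' Coordinates are 1-based continuous positions in the matrix index system
#' (`y` = row, `x` = column). Positions outside the image are clamped to
#' the border pixel.
#'
#' @param img numeric matrix.
#' @param y,x numeric vectors of equal length.
#' @return numeric vector of interpolated values.
#' @export
bilinear_interp <- function(img, y, x) {
  stopifnot(is.matrix(img), length(y) == length(x))
  ny <- nrow(img); nx <- ncol(img)
  y <- pmin(pmax(y, 1), ny)
  x <- pmin(pmax(x, 1), nx)
  y0 <- pmin(floor(y), ny - 1L); x0 <- pmin(floor(x), nx - 1L)
  if (ny == 1L) y0 <- rep(1, length(y))
  if (nx == 1L) x0 <- rep(1, length(x))
  fy <- y - y0; fx <- x - x0
  y1 <- pmin(y0 + 1L, ny); x1 <- pmin(x0 + 1L, nx)
  v00 <- img[cbind(y0, x0)]; v01 <- img[cbind(y0, x1)]
  v10 <- img[cbind(y1, x0)]; v11 <- img[cbind(y1, x1)]
  (1 - fy) * ((1 - fx) * v00 + fx * v01) + fy * ((1 - fx) * v10 + fx * v11)
}

# Shared 256-bin histogram used by the automatic thresholds. Returns the
# counts and the bin-centre grey levels, mirroring common image-analysis
# practice of thresholding on a fixed-resolution intensity histogram.
threshold_histogram <- function(x, nbins = 256L) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) stop("no finite values to threshold")
  rng <- range(x)
  if (diff(rng) == 0) return(list(counts = length(x), centers = rng[1]))
  breaks <- seq(rng[1], rng[2], length.out = nbins + 1L)
  counts <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE),
                     nbins = nbins)
  centers <- (breaks[-1] + breaks[-length(breaks)]) / 2
  list(counts = counts, centers = centers)
}

#' Yen automatic threshold
#'
#' Maximum-correlation criterion of Yen, Chang and Chang (1995), computed
#' on a 256-bin histogram. Returns the grey level separating background
#' from foreground; voxels strictly above it are foreground.
#'
#' @param x numeric vector (or array) of intensities.
#' @return scalar threshold.
#' @export
threshold_yen <- function(x) {
  h <- threshold_histogram(x)
  if (length(h$counts) == 1L) return(h$centers[1])
  p <- h$counts / sum(h$counts)
  p1 <- cumsum(p)
  p2 <- cumsum(p^2)
  p2r <- sum(p^2) - p2
  crit <- -log(pmax(p2 * p2r, .Machine$double.xmin)) +
    2 * log(pmax(p1 * (1 - p1), .Machine$double.xmin))
  h$centers[which.max(crit)]
}

#' Li automatic threshold
#'
#' Minimum cross-entropy threshold of Li and Lee (1993), via the iterative
#' scheme of Li and Tam (1998) on a 256-bin histogram.
#'
#' @param x numeric vector (or array) of intensities.
#' @return scalar threshold.
#' @export
threshold_li <- function(x) {
  h <- threshold_histogram(x)
  if (length(h$counts) == 1L) return(h$centers[1])
  counts <- h$counts; centers <- h$centers
  # work on strictly positive shifted levels so logs are defined
  shift <- if (min(centers) <= 0) -min(centers) + 1e-8 * diff(range(centers)) else 0
  g <- centers + shift
  t_new <- sum(counts * g) / sum(counts)  # start at the image mean
  eps <- diff(range(g)) * 1e-7
  for (i in 1:200) {
    t_old <- t_new
    lo <- g <= t_old
    n_lo <- sum(counts[lo]); n_hi <- sum(counts[!lo])
    if (n_lo == 0 || n_hi == 0) break
    m_lo <- sum(counts[lo] * g[lo]) / n_lo
    m_hi <- sum(counts[!lo] * g[!lo]) / n_hi
    if (m_lo <= 0 || m_hi <= 0 || abs(log(m_lo) - log(m_hi)) < 1e-12) break
    t_new <- (m_lo - m_hi) / (log(m_lo) - log(m_hi))
    if (abs(t_new - t_old) < eps) break
  }
  t_new - shift
}

#' Label connected components in a 3D binary mask (26-connectivity)
#'
#' Foreground voxels are grouped into components using full 3D
#' 26-neighbourhood connectivity. Labels are assigned in decreasing order
#' of component size (label 1 = largest).
#'
#' @param mask logical or 0/1 array `(y, x, z)`.
#' @return integer array of the same dimensions; 0 = background.
#' @export
label_components_3d <- function(mask) {
  d <- dim(mask)
  stopifnot(length(d) == 3L)
  fg <- which(mask > 0)
  lab <- array(0L, dim = d)
  if (length(fg) == 0L) return(lab)
  # map linear voxel index -> foreground vertex id
  vid <- integer(prod(d))
  vid[fg] <- seq_along(fg)
  coords <- arrayInd(fg, d)
  offs <- expand.grid(dy = -1:1, dx = -1:1, dz = -1:1)
  offs <- offs[offs$dy != 0 | offs$dx != 0 | offs$dz != 0, ]
  # half the offsets suffice for an undirected graph
  offs <- offs[1:(nrow(offs) / 2), ]
  edges <- vector("list", nrow(offs))
  for (k in seq_len(nrow(offs))) {
    ny <- coords[, 1] + offs$dy[k]
    nx <- coords[, 2] + offs$dx[k]
    nz <- coords[, 3] + offs$dz[k]
    ok <- ny >= 1 & ny <= d[1] & nx >= 1 & nx <= d[2] & nz >= 1 & nz <= d[3]
    if (!any(ok)) next
    lin <- (nz[ok] - 1L) * d[1] * d[2] + (nx[ok] - 1L) * d[1] + ny[ok]
    nb <- vid[lin]
    keep <- nb > 0L
    if (!any(keep)) next
    edges[[k]] <- rbind(which(ok)[keep], nb[keep])
  }
  em <- do.call(cbind, edges)
  g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
  if (!is.null(em) && ncol(em) > 0) g <- igraph::add_edges(g, as.vector(em))
  comp <- igraph::components(g)
  # relabel by decreasing size, ties broken by first occurrence
  sizes <- comp$csize
  ord <- order(-sizes, seq_along(sizes))
  relab <- integer(length(sizes)); relab[ord] <- seq_along(sizes)
  lab[fg] <- relab[comp$membership]
  lab
}

# condition constructors for named errors
cr_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "chromrings_error")))
}
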