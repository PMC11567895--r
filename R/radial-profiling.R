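# Radial chromatin profiling: centre-to-contour ray sampling, per-ray
# distance normalization, 5%-wide binning, max-normalization, and
# condition averaging with a confidence band. Distances run from the
# nucleolus centre (0%) to the nuclear contour (100%).

#' Extract the ordered boundary contour of a 2D mask
#'
#' Returns the closed, ordered polygon of boundary pixels of a single
#' connected region, as 1-based `(y, x)` matrix rows.
#'
#' @param mask2d binary matrix (rows = y, columns = x).
#' @return numeric matrix with columns `y`, `x`.
#' @export
extract_contour <- function(mask2d) {
  stopifnot(is.matrix(mask2d))
  m <- (mask2d > 0) * 1L
  if (!any(m > 0)) cr_error("empty mask", "empty_mask")
  lab <- EBImage::bwlabel(m)
  if (max(lab) > 1L)
    cr_error("mask has multiple connected components", "multi_component_mask")
  oc <- EBImage::ocontour(m)[[1]]  # 0-based (row, col)
  out <- cbind(y = oc[, 1] + 1, x = oc[, 2] + 1)
  storage.mode(out) <- "double"
  out
}

# Even-odd point-in-polygon test (polygon rows = (y, x)).
point_in_polygon <- function(py, px, poly) {
  n <- nrow(poly)
  if (n < 3) {
    # degenerate contours (1-2 px masks): fall back to proximity
    return(min(sqrt((poly[, 1] - py)^2 + (poly[, 2] - px)^2)) <= 1)
  }
  j <- c(n, seq_len(n - 1L))
  yi <- poly[, 1]; xi <- poly[, 2]
  yj <- poly[j, 1]; xj <- poly[j, 2]
  cross <- ((yi > py) != (yj > py)) &
    (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
  sum(cross) %% 2L == 1L
}

#' Sample intensity rays from a centre to every contour point
#'
#' One ray per contour vertex. Intensities are sampled by bilinear
#' interpolation every `step` voxels along the segment from `center` to
#' the contour point, with the final sample exactly at the contour point.
#' If a nucleolus mask is supplied, each ray also records the distance at
#' which it crosses the nucleolus edge (midpoint of the last inside and
#' first outside sample).
#'
#' @param plane 2D intensity matrix.
#' @param center length-2 `(y, x)` position (1-based, may be fractional);
#'   must lie strictly inside the contour.
#' @param contour matrix from [extract_contour()].
#' @param step sampling step in voxels (default 0.5).
#' @param nucleolus_mask optional binary matrix marking the nucleolus.
#' @return object of class `radial_rays`: a list with `samples`
#'   (data.frame `ray`, `dist`, `intensity`), per-ray `lengths`, and
#'   `edge_crossing` (voxels; `NA` if a ray never leaves the mask,
#'   `NULL` if no mask was given).
#' @export
sample_rays <- function(plane, center, contour, step = 0.5,
                        nucleolus_mask = NULL) {
  stopifnot(is.matrix(plane), length(center) == 2L, step > 0)
  cy <- center[[1]]; cx <- center[[2]]
  if (!point_in_polygon(cy, cx, contour))
    cr_error("center is not inside the contour", "center_outside_contour")
  nray <- nrow(contour)
  lens <- sqrt((contour[, 1] - cy)^2 + (contour[, 2] - cx)^2)
  dist_list <- lapply(seq_len(nray), function(i) {
    L <- lens[i]
    if (L == 0) return(0)
    d <- seq(0, L, by = step)
    if (d[length(d)] < L) d <- c(d, L)
    d
  })
  counts <- lengths(dist_list)
  ray <- rep(seq_len(nray), counts)
  dist <- unlist(dist_list, use.names = FALSE)
  frac <- ifelse(lens[ray] > 0, dist / lens[ray], 0)
  yy <- cy + (contour[ray, 1] - cy) * frac
  xx <- cx + (contour[ray, 2] - cx) * frac
  intensity <- bilinear_interp(plane, yy, xx)
  edge <- NULL
  if (!is.null(nucleolus_mask)) {
    iy <- pmin(pmax(round(yy), 1L), nrow(nucleolus_mask))
    ix <- pmin(pmax(round(xx), 1L), ncol(nucleolus_mask))
    inside <- nucleolus_mask[cbind(iy, ix)] > 0
    edge <- vapply(seq_len(nray), function(i) {
      sel <- which(ray == i)
      ins <- inside[sel]
      if (!ins[1]) return(0)          # origin already outside the nucleolus
      first_out <- match(FALSE, ins)
      if (is.na(first_out)) return(NA_real_)  # never exits
      (dist[sel][first_out - 1L] + dist[sel][first_out]) / 2
    }, numeric(1))
  }
  structure(list(samples = data.frame(ray = ray, dist = dist,
                                      intensity = intensity),
                 lengths = lens, edge_crossing = edge, center = c(cy, cx),
                 step = step),
            class = "radial_rays")
}

#' @export
print.radial_rays <- function(x, ...) {
  cat("<radial_rays>", length(x$lengths), "rays,",
      nrow(x$samples), "samples\n")
  cat(sprintf("  ray length: %.1f-%.1f voxels; step %.2f\n",
              min(x$lengths), max(x$lengths), x$step))
  if (!is.null(x$edge_crossing))
    cat("  nucleolus edge crossings recorded\n")
  invisible(x)
}

#' Discard rays too short to resolve two peaks
#'
#' Retains only rays whose nucleolar-edge-to-contour segment is at least
#' `min_length` voxels (default 9, the resolution limit estimated for
#' muscle nuclei). The number of discarded rays is recorded in the
#' `discarded` attribute; an empty result triggers a warning.
#'
#' @param rays a `radial_rays` object carrying edge crossings.
#' @param min_length minimum resolvable edge-to-contour length (voxels).
#' @return filtered `radial_rays`.
#' @export
filter_resolvable_rays <- function(rays, min_length = 9) {
  stopifnot(inherits(rays, "radial_rays"), min_length >= 0)
  if (is.null(rays$edge_crossing))
    cr_error("rays carry no nucleolus-edge crossing information",
             "missing_edge_crossing")
  seg <- rays$lengths - rays$edge_crossing
  keep <- which(!is.na(seg) & seg >= min_length)
  if (length(keep) == 0L)
    warning("no rays pass the resolvability filter")
  sel <- rays$samples$ray %in% keep
  new_id <- match(rays$samples$ray[sel], keep)
  out <- structure(list(
    samples = data.frame(ray = new_id, dist = rays$samples$dist[sel],
                         intensity = rays$samples$intensity[sel]),
    lengths = rays$lengths[keep],
    edge_crossing = rays$edge_crossing[keep],
    center = rays$center, step = rays$step), class = "radial_rays")
  attr(out, "discarded") <- length(rays$lengths) - length(keep)
  out
}

#' Bin ray samples into a 20-bin normalized radial profile
#'
#' Each ray's sample distances are divided by that ray's centre-to-contour
#' length (0% centre, 100% contour). Samples are assigned to 5%-wide
#' half-open bins (`[0,5)` -> centre 2.5%, ..., `[95,100]` -> 97.5%, last
#' bin closed). `method = "pooled"` averages all samples falling in a bin;
#' `method = "per_ray"` first averages within each ray, then across rays.
#' The binned profile is finally divided by its maximum.
#'
#' @param rays a `radial_rays` object (>= 1 ray).
#' @param method `"pooled"` (default) or `"per_ray"`.
#' @param normalize divide by the profile maximum (default `TRUE`).
#' @param nucleus_id optional identifier stored on the profile.
#' @return object of class `binned_profile`: bin `centers` (percent),
#'   `intensity`, per-bin sample counts `n_samples`, `normalized` flag,
#'   and `interpolated` flags for bins filled from their neighbours.
#' @export
bin_and_normalize <- function(rays, method = c("pooled", "per_ray"),
                              normalize = TRUE, nucleus_id = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(rays, "radial_rays"))
  if (length(rays$lengths) < 1L) cr_error("no rays", "empty_input")
  if (any(rays$lengths <= 0)) cr_error("ray of zero length", "zero_length_ray")
  s <- rays$samples
  rel <- s$dist / rays$lengths[s$ray]
  bin <- pmin(floor(rel / 0.05) + 1L, 20L)
  centers <- seq(2.5, 97.5, by = 5)
  n_samples <- tabulate(bin, nbins = 20L)
  if (method == "pooled") {
    sums <- vapply(1:20, function(b) sum(s$intensity[bin == b]), numeric(1))
    intensity <- ifelse(n_samples > 0, sums / n_samples, NA_real_)
  } else {
    key <- interaction(s$ray, bin, drop = TRUE)
    per <- tapply(s$intensity, key, mean)
    ids <- do.call(rbind, strsplit(names(per), ".", fixed = TRUE))
    bin_of <- as.integer(ids[, 2])
    intensity <- vapply(1:20, function(b) {
      v <- per[bin_of == b]
      if (length(v) == 0) NA_real_ else mean(v)
    }, numeric(1))
  }
  interpolated <- is.na(intensity)
  if (any(interpolated)) {
    filled_n <- sum(!interpolated)
    if (filled_n == 0L) cr_error("all bins empty", "empty_input")
    if (filled_n == 1L) {
      intensity[interpolated] <- intensity[!interpolated]
    } else {
      filled <- stats::approx(centers[!interpolated],
                              intensity[!interpolated],
                              xout = centers, rule = 2)$y
      intensity[interpolated] <- filled[interpolated]
    }
  }
  normalized <- FALSE
  if (normalize) {
    mx <- max(intensity)
    if (mx > 0) {
      intensity <- intensity / mx
      normalized <- TRUE
    } else {
      warning("all-zero profile; max-normalization skipped")
    }
  }
  structure(list(centers = centers, intensity = intensity,
                 n_samples = n_samples, normalized = normalized,
                 interpolated = interpolated, nucleus_id = nucleus_id),
            class = "binned_profile")
}

#' @export
print.binned_profile <- function(x, ...) {
  cat("<binned_profile>", if (!is.null(x$nucleus_id)) x$nucleus_id else "",
      "\n  20 bins (2.5-97.5%),",
      if (x$normalized) "max-normalized" else "raw", "\n")
  print(round(stats::setNames(x$intensity, paste0(x$centers, "%")), 3))
  invisible(x)
}

#' Average single-nucleus profiles into a condition profile
#'
#' Per-bin mean across nuclei with a 95% confidence band
#' `mean +/- z * SD/sqrt(n)` (normal approximation). With a single
#' profile the half-width is zero and flagged.
#'
#' @param profiles list of max-normalized `binned_profile` objects.
#' @param level confidence level (default 0.95).
#' @param condition optional condition label.
#' @return object of class `condition_profile` with `centers`, `mean`,
#'   `half_width`, `n`.
#' @export
condition_profile <- function(profiles, level = 0.95, condition = NULL) {
  stopifnot(is.list(profiles), length(profiles) >= 1L)
  if (inherits(profiles, "binned_profile")) profiles <- list(profiles)
  norms <- vapply(profiles, function(p) p$normalized, logical(1))
  if (length(unique(norms)) > 1L)
    cr_error("profiles mix normalized and unnormalized states",
             "mixed_normalization")
  mat <- do.call(rbind, lapply(profiles, function(p) p$intensity))
  n <- nrow(mat)
  mu <- colMeans(mat)
  z <- stats::qnorm(1 - (1 - level) / 2)
  if (n == 1L) {
    half <- rep(0, ncol(mat))
    warning("single profile: confidence half-width set to 0")
  } else {
    half <- z * apply(mat, 2, stats::sd) / sqrt(n)
  }
  structure(list(centers = profiles[[1]]$centers, mean = mu,
                 half_width = half, n = n, level = level,
                 condition = condition),
            class = "condition_profile")
}

#' @export
print.condition_profile <- function(x, ...) {
  cat("<condition_profile>",
      if (!is.null(x$condition)) x$condition else "", "n =", x$n, "\n")
  m <- rbind(mean = round(x$mean, 3), half_width = round(x$half_width, 3))
  colnames(m) <- paste0(x$centers, "%")
  print(m)
  invisible(x)
}

#' Plot a condition-average radial profile with its confidence band
#' @param x a `condition_profile`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.condition_profile <- function(x, ...) {
  graphics::plot(x$centers, x$mean, type = "l", lwd = 2,
                 xlab = "distance from nucleolus centre (%)",
                 ylab = "normalized intensity",
                 ylim = range(c(x$mean - x$half_width,
                                x$mean + x$half_width)), ...)
  graphics::polygon(c(x$centers, rev(x$centers)),
                    c(x$mean - x$half_width, rev(x$mean + x$half_width)),
                    col = grDevices::adjustcolor("grey50", 0.3), border = NA)
  invisible(x)
}

#' Radial profile in absolute distance from the nucleolus edge
#'
#' Re-expresses each ray's samples as micrometre distances beyond that
#' ray's nucleolus-edge crossing (samples inside the nucleolus are
#' discarded) and averages them in fixed-width bins. Rays that never exit
#' the nucleolus mask are excluded with a warning.
#'
#' @param rays `radial_rays` with edge crossings (origin at the nucleolus
#'   centroid).
#' @param voxel_xy pixel pitch in um.
#' @param bin_width_um bin width in um (default 0.25).
#' @return object of class `edge_profile`: `centers_um`, `intensity`,
#'   `n_samples`.
#' @export
nucleolus_edge_profile <- function(rays, voxel_xy, bin_width_um = 0.25) {
  stopifnot(inherits(rays, "radial_rays"), voxel_xy > 0, bin_width_um > 0)
  if (is.null(rays$edge_crossing))
    cr_error("rays carry no nucleolus-edge crossing information",
             "missing_edge_crossing")
  bad <- which(is.na(rays$edge_crossing))
  if (length(bad) > 0)
    warning(length(bad), " ray(s) never exit the nucleolus mask; excluded")
  s <- rays$samples
  keep <- !(s$ray %in% bad)
  s <- s[keep, ]
  d_um <- (s$dist - rays$edge_crossing[s$ray]) * voxel_xy
  s <- s[d_um >= 0, ]
  d_um <- d_um[d_um >= 0]
  if (nrow(s) == 0L) cr_error("no samples beyond the nucleolus edge",
                              "empty_input")
  bin <- floor(d_um / bin_width_um) + 1L
  nb <- max(bin)
  n_samples <- tabulate(bin, nbins = nb)
  sums <- vapply(seq_len(nb), function(b) sum(s$intensity[bin == b]),
                 numeric(1))
  intensity <- ifelse(n_samples > 0, sums / n_samples, NA_real_)
  structure(list(centers_um = (seq_len(nb) - 0.5) * bin_width_um,
                 intensity = intensity, n_samples = n_samples),
            class = "edge_profile")
}

#' Compute the binned radial profile of one synthetic or loaded scene
#'
#' Convenience pipeline: central-plane extraction, contour, ray sampling
#' from the nucleolus-centre annotation, optional resolvability
#' filtering, binning and max-normalization.
#'
#' @param scene a `nucleus_scene` (or a list with compatible fields).
#' @param channel channel name (default `"chromatin"`).
#' @param step ray sampling step in voxels.
#' @param min_ray_length if non-`NULL`, apply [filter_resolvable_rays()]
#'   with this minimum nucleolar-edge-to-contour length (voxels); the
#'   nucleolus mask is then required.
#' @param nucleolus_mask2d optional 2D nucleolus mask for edge crossings
#'   (defaults to the scene's truth mask when available and needed).
#' @param use_3d_mask derive the analysis plane from the 3D mask via
#'   [central_plane_from_3d()] instead of using the stored 2D mask.
#' @param method binning method, see [bin_and_normalize()].
#' @return `binned_profile`.
#' @export
profile_scene <- function(scene, channel = "chromatin", step = 0.5,
                          min_ray_length = NULL, nucleolus_mask2d = NULL,
                          use_3d_mask = FALSE,
                          method = c("pooled", "per_ray")) {
  method <- match.arg(method)
  if (use_3d_mask) {
    cp <- central_plane_from_3d(scene$mask3d)
    z <- cp$z_index; mask2d <- cp$mask2d
  } else {
    z <- scene$central_z; mask2d <- scene$mask2d
  }
  plane <- scene$channels[[channel]][, , z]
  contour <- extract_contour(mask2d)
  need_edge <- !is.null(min_ray_length) || !is.null(nucleolus_mask2d)
  if (need_edge && is.null(nucleolus_mask2d) &&
      inherits(scene, "nucleus_scene")) {
    nucleolus_mask2d <- nucleolus_truth_mask(scene)[, , z]
  }
  rays <- sample_rays(plane, scene$nucleolus_center[c("y", "x")], contour,
                      step = step, nucleolus_mask = nucleolus_mask2d)
  if (!is.null(min_ray_length))
    rays <- filter_resolvable_rays(rays, min_ray_length)
  bin_and_normalize(rays, method = method, nucleus_id = scene$nucleus_id)
}

#' Profile every scene of a cohort
#'
#' @param scenes list of scenes (e.g. from [generate_cohort()]).
#' @param ... passed to [profile_scene()].
#' @return list of `binned_profile`s; the `condition` attribute of each
#'   element records the scene's condition label.
#' @export
profile_cohort <- function(scenes, ...) {
  lapply(scenes, function(sc) {
    p <- profile_scene(sc, ...)
    attr(p, "condition") <- sc$condition
    p
  })
}
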