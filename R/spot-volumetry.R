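# Nucleolus and FISH spot detection in 3D, 3D Gaussian fitting with
# ellipsoid volumetry, background-corrected integrated FISH intensity,
# and projected nucleolar/nuclear areas.

#' Stack a 2D mask into a 3D cylindrical object
#'
#' Replicates a 2D central-plane mask across a range of z slices, the
#' standard bridge from 2D nuclear segmentation to a 3D search volume.
#'
#' @param mask2d binary matrix.
#' @param z_range integer vector of slice indices (1-based).
#' @param n_z total number of slices in the target stack (defaults to
#'   `max(z_range)`).
#' @return 0/1 integer array `(y, x, z)` with `n_z` slices.
#' @export
stack_cylinder <- function(mask2d, z_range, n_z = max(z_range)) {
  stopifnot(is.matrix(mask2d))
  if (!any(mask2d > 0)) cr_error("empty mask", "empty_mask")
  z_range <- as.integer(z_range)
  if (any(z_range < 1L) || any(z_range > n_z))
    cr_error("z_range outside the stack", "invalid_parameter")
  out <- array(0L, dim = c(dim(mask2d), n_z))
  m <- (mask2d > 0) * 1L
  for (k in z_range) out[, , k] <- m
  out
}

#' Extend a 2D mask a fixed number of slices above and below
#'
#' Spans `central_z - n_slices` to `central_z + n_slices` (up to
#' `2 * n_slices + 1` slices; 10 slices of 200 nm each by default),
#' clipped at the stack bounds. Clipping is reported via the `clipped`
#' attribute, not an error.
#'
#' @param mask2d binary matrix.
#' @param central_z central slice (1-based, inside the stack).
#' @param n_z total slices in the stack.
#' @param n_slices slices added on each side (default 10).
#' @return 0/1 integer array with attributes `z_range` and `clipped`.
#' @export
extend_mask_z <- function(mask2d, central_z, n_z, n_slices = 10) {
  stopifnot(is.matrix(mask2d), n_slices >= 0)
  if (central_z < 1 || central_z > n_z)
    cr_error("central_z outside the stack", "invalid_parameter")
  lo <- max(1L, central_z - n_slices)
  hi <- min(n_z, central_z + n_slices)
  clipped <- (central_z - n_slices < 1L) || (central_z + n_slices > n_z)
  out <- stack_cylinder(mask2d, lo:hi, n_z = n_z)
  attr(out, "z_range") <- c(lo, hi)
  attr(out, "clipped") <- clipped
  out
}

#' Detect bright spots in a 3D stack by smoothing and auto-thresholding
#'
#' Smooths the stack with a small 3D Gaussian (default sigma 0.75 voxel),
#' thresholds the smoothed signal inside the search mask with the Yen or
#' Li algorithm, and labels connected components with full 26-neighbour
#' 3D connectivity. `method = "auto"` tries Yen first and falls back to
#' Li when Yen yields no component, more than 5, or only components
#' below a plausible spot size (10 voxels); the choice is recorded. A threshold that leaves no foreground returns an empty
#' segmentation with a warning.
#'
#' @param stack numeric array `(y, x, z)`.
#' @param search_mask binary array of the same dimensions; thresholding
#'   and labelling are restricted to it.
#' @param smoothing_sigma isotropic smoothing sigma in voxels.
#' @param method `"auto"`, `"yen"` or `"li"`.
#' @return object of class `spot_segmentation`: `labels` (integer array,
#'   0 = background, 1 = largest component), `method`, `threshold`,
#'   `voxel_counts`.
#' @export
detect_spots <- function(stack, search_mask, smoothing_sigma = 0.75,
                         method = c("auto", "yen", "li")) {
  method <- match.arg(method)
  stopifnot(identical(dim(stack), dim(search_mask)))
  if (!any(search_mask > 0)) cr_error("empty search mask", "empty_mask")
  sm <- if (smoothing_sigma > 0) gaussian_blur_3d(stack, smoothing_sigma)
        else stack
  vals <- sm[search_mask > 0]
  run <- function(meth) {
    thr <- if (meth == "yen") threshold_yen(vals) else threshold_li(vals)
    fg <- (sm > thr) & (search_mask > 0)
    lab <- label_components_3d(fg)
    list(thr = thr, lab = lab, n = max(lab))
  }
  if (method == "auto") {
    res <- run("yen"); used <- "yen"
    biggest <- if (res$n > 0) max(tabulate(res$lab[res$lab > 0], res$n)) else 0
    # Yen can lock onto the histogram peak of a smooth blob and leave
    # only a few supra-threshold voxels; no plausible spot is that small
    if (res$n == 0 || res$n > 5 || biggest < 10) {
      res <- run("li"); used <- "li"
    }
  } else {
    res <- run(method); used <- method
  }
  if (res$n == 0) warning("threshold yields no foreground; empty segmentation")
  counts <- if (res$n > 0) tabulate(res$lab[res$lab > 0], nbins = res$n)
            else integer(0)
  structure(list(labels = res$lab, method = used, threshold = res$thr,
                 voxel_counts = counts),
            class = "spot_segmentation")
}

#' @export
print.spot_segmentation <- function(x, ...) {
  cat("<spot_segmentation>", length(x$voxel_counts), "component(s),",
      "method:", x$method, sprintf("(threshold %.3g)\n", x$threshold))
  if (length(x$voxel_counts) > 0)
    cat("  voxels per label:", paste(x$voxel_counts, collapse = ", "), "\n")
  invisible(x)
}

#' Select the nucleolus label from a spot segmentation
#'
#' Returns the component containing the annotated nucleolus centre; if
#' the annotation is in the background (or absent), the largest component
#' overlapping the nucleus mask. The selection rule applied is recorded
#' in the `rule` attribute.
#'
#' @param seg a `spot_segmentation`.
#' @param annotation optional `(y, x, z)` voxel coordinate (1-based).
#' @param nucleus_mask optional binary array for the overlap fallback.
#' @return 0/1 integer array of the selected component, with attributes
#'   `label` and `rule`.
#' @export
select_nucleolus <- function(seg, annotation = NULL, nucleus_mask = NULL) {
  stopifnot(inherits(seg, "spot_segmentation"))
  if (length(seg$voxel_counts) == 0L)
    cr_error("empty segmentation", "empty_segmentation")
  lab <- seg$labels
  pick <- 0L; rule <- NA_character_
  if (!is.null(annotation)) {
    a <- round(annotation)
    pick <- lab[a[[1]], a[[2]], a[[3]]]
    if (pick > 0L) rule <- "annotation"
  }
  if (pick == 0L) {
    if (is.null(nucleus_mask))
      cr_error("annotation not inside any label and no nucleus mask given",
               "label_not_found")
    overlap <- vapply(seq_along(seg$voxel_counts), function(l)
      sum(lab == l & nucleus_mask > 0), numeric(1))
    if (all(overlap == 0))
      cr_error("no label overlaps the nucleus mask", "label_not_found")
    pick <- which.max(overlap)
    rule <- "largest_overlap"
  }
  out <- (lab == pick) * 1L
  attr(out, "label") <- pick
  attr(out, "rule") <- rule
  out
}

gaussian3d_model <- function(par, yy, xx, zz) {
  par[["A"]] *
    exp(-(yy - par[["y_c"]])^2 / (2 * par[["sigma_y"]]^2)) *
    exp(-(xx - par[["x_c"]])^2 / (2 * par[["sigma_x"]]^2)) *
    exp(-(zz - par[["z_c"]])^2 / (2 * par[["sigma_z"]]^2)) + par[["B"]]
}

#' Fit a separable 3D Gaussian to a segmented spot
#'
#' Least-squares fit of `g(x, y, z) = g(x) g(y) g(z) + B` (each factor a
#' 1D Gaussian sharing amplitude `A`) to the raw, unsmoothed voxel
#' intensities inside the segmentation mask. The fitted sigmas give the
#' ellipsoid volume `V = (4/3) pi sigma_z sigma_y sigma_x`, reported in
#' voxel^3 and, when voxel pitches are supplied, in um^3 (the um^3 value
#' is the voxel^3 value times `voxel_xy^2 * voxel_z`). Initialization is
#' the intensity-weighted centroid and second moments of the mask.
#'
#' @param stack numeric array `(y, x, z)` of raw intensities.
#' @param spot_mask binary array; needs >= 10 voxels.
#' @param voxel_xy,voxel_z voxel pitches in um (default 1: volumes in
#'   voxel units only).
#' @return object of class `gaussian3d_fit` with `coefficients`
#'   (`A, B, y_c, x_c, z_c, sigma_y, sigma_x, sigma_z`), `volume_vox`,
#'   `volume_um3`, `rss`, `converged`.
#' @export
fit_gaussian3d <- function(stack, spot_mask, voxel_xy = 1, voxel_z = 1) {
  stopifnot(identical(dim(stack), dim(spot_mask)))
  idx <- which(spot_mask > 0)
  if (length(idx) < 10L)
    cr_error("spot mask has fewer than 10 voxels", "too_few_voxels")
  co <- arrayInd(idx, dim(stack))
  v <- stack[idx]
  w <- pmax(v - min(v), 0)
  if (sum(w) == 0) w <- rep(1, length(v))
  ctr <- colSums(co * w) / sum(w)
  mom <- sqrt(pmax(colSums((co - rep(ctr, each = nrow(co)))^2 * w) / sum(w),
                   0.25))
  start <- c(A = max(v) - min(v), B = min(v),
             y_c = ctr[1], x_c = ctr[2], z_c = ctr[3],
             sigma_y = mom[1], sigma_x = mom[2], sigma_z = mom[3])
  d <- dim(stack)
  lower <- c(A = 0, B = 0, y_c = 1, x_c = 1, z_c = 1,
             sigma_y = 0.1, sigma_x = 0.1, sigma_z = 0.1)
  upper <- c(A = 2 * max(v), B = max(min(v), 1e-12), y_c = d[1], x_c = d[2],
             z_c = d[3], sigma_y = 2 * d[1], sigma_x = 2 * d[2],
             sigma_z = 2 * d[3])
  # start strictly inside the box: a parameter beginning exactly on a
  # bound stays frozen there in the bounded Levenberg-Marquardt update
  gap <- 1e-3 * pmax(upper - lower, 1e-9)
  start <- pmin(pmax(start, lower + gap), upper - gap)
  fit <- minpack.lm::nls.lm(
    par = start,
    fn = function(p, yy, xx, zz, v) v - gaussian3d_model(p, yy, xx, zz),
    lower = lower, upper = upper,
    yy = co[, 1], xx = co[, 2], zz = co[, 3], v = v,
    control = minpack.lm::nls.lm.control(maxiter = 500))
  par <- stats::setNames(as.numeric(fit$par), names(start))
  vol_vox <- 4 / 3 * pi * par[["sigma_y"]] * par[["sigma_x"]] * par[["sigma_z"]]
  structure(list(coefficients = par,
                 volume_vox = vol_vox,
                 volume_um3 = vol_vox * voxel_xy^2 * voxel_z,
                 voxel_xy = voxel_xy, voxel_z = voxel_z,
                 rss = sum(fit$fvec^2),
                 converged = fit$info %in% 1:4, info = fit$info,
                 n_voxels = length(idx)),
            class = "gaussian3d_fit")
}

#' @export
coef.gaussian3d_fit <- function(object, ...) object$coefficients

#' @export
print.gaussian3d_fit <- function(x, digits = 4, ...) {
  cat("3D Gaussian spot fit (", x$n_voxels, "voxels )\n")
  print(round(x$coefficients, digits))
  cat(sprintf("volume: %.4g voxel^3", x$volume_vox))
  if (x$voxel_xy != 1 || x$voxel_z != 1)
    cat(sprintf(" = %.4g um^3", x$volume_um3))
  cat(if (x$converged) "  (converged)\n" else "  (NOT converged)\n")
  invisible(x)
}

#' @export
summary.gaussian3d_fit <- function(object, ...) {
  print(object)
  cat("RSS:", format(object$rss, digits = 4), "\n")
  invisible(object)
}

#' Nucleolar volumes relative to a control cohort
#'
#' Divides each treated volume by the control median and compares the two
#' volume sets with a standard two-sided Wilcoxon rank-sum test.
#'
#' @param treated,control numeric vectors of volumes (same units).
#' @return list with `ratios`, `median_ratio`, `p_value`, `test`.
#' @export
relative_volume <- function(treated, control) {
  stopifnot(length(treated) >= 1, length(control) >= 1)
  ctrl_med <- stats::median(control)
  if (ctrl_med == 0) cr_error("control median volume is zero", "invalid_input")
  wt <- stats::wilcox.test(treated, control, alternative = "two.sided",
                           exact = FALSE)
  list(ratios = treated / ctrl_med,
       median_ratio = stats::median(treated / ctrl_med),
       p_value = wt$p.value, test = wt)
}

#' Background-corrected integrated FISH signal
#'
#' Sums raw voxel values over all segmented spot voxels and subtracts
#' `voxel count x background median`, where the background median is
#' taken over the central-slice pixels that are inside the nucleus but
#' outside the segmented objects.
#'
#' @param stack numeric array `(y, x, z)`.
#' @param spots a `spot_segmentation` (or a label/binary array).
#' @param nucleus_mask3d binary array delimiting the nucleus.
#' @param central_z central slice used for the background estimate.
#' @return object of class `fish_quant`: `corrected_sum`, `raw_sum`,
#'   `background_median`, `n_voxels`.
#' @export
integrated_fish_signal <- function(stack, spots, nucleus_mask3d, central_z) {
  lab <- if (inherits(spots, "spot_segmentation")) spots$labels else spots
  stopifnot(identical(dim(stack), dim(lab)),
            identical(dim(stack), dim(nucleus_mask3d)))
  spot_vox <- lab > 0
  bg_sel <- nucleus_mask3d[, , central_z] > 0 & !spot_vox[, , central_z]
  if (!any(bg_sel))
    cr_error("no in-nucleus background pixels at the central slice",
             "no_background")
  bg_med <- stats::median(stack[, , central_z][bg_sel])
  n_vox <- sum(spot_vox)
  raw <- sum(stack[spot_vox])
  structure(list(corrected_sum = raw - n_vox * bg_med, raw_sum = raw,
                 background_median = bg_med, n_voxels = n_vox),
            class = "fish_quant")
}

#' @export
print.fish_quant <- function(x, ...) {
  cat("<fish_quant> corrected sum:", format(x$corrected_sum, digits = 6),
      "\n  raw:", format(x$raw_sum, digits = 6),
      " background median:", format(x$background_median, digits = 6),
      " voxels:", x$n_voxels, "\n")
  invisible(x)
}

#' Projected nucleolar area, nuclear area and their ratio
#'
#' Max-projects the 3D nucleolus mask along z and multiplies pixel counts
#' by the pixel area; the nuclear area comes from the 2D central-plane
#' mask.
#'
#' @param nucleolus_mask3d binary array `(y, x, z)`.
#' @param nucleus_mask2d binary matrix.
#' @param voxel_xy pixel pitch (um); default 1 gives areas in px^2.
#' @return list with `nucleolus_area`, `nucleus_area`, `ratio`.
#' @export
nucleolar_nuclear_area <- function(nucleolus_mask3d, nucleus_mask2d,
                                   voxel_xy = 1) {
  stopifnot(length(dim(nucleolus_mask3d)) == 3L, is.matrix(nucleus_mask2d))
  proj <- apply(nucleolus_mask3d, c(1, 2), max)
  if (!any(proj > 0)) cr_error("empty nucleolus projection", "empty_mask")
  if (!any(nucleus_mask2d > 0)) cr_error("empty nucleus mask", "empty_mask")
  a_nucleolus <- sum(proj > 0) * voxel_xy^2
  a_nucleus <- sum(nucleus_mask2d > 0) * voxel_xy^2
  list(nucleolus_area = a_nucleolus, nucleus_area = a_nucleus,
       ratio = a_nucleolus / a_nucleus)
}
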