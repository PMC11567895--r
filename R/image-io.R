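# Reading and writing scene bundles (multi-page TIFF stacks, label
# masks, annotation tables, truth sidecars), profile/result tables, and
# the 3D-to-2D central-plane bridge.
#
# Conventions: in-memory arrays are 1-based `(y, x, z)`; all coordinates
# in files are 0-based voxel indices in axis order (z, y, x). Stacks are
# stored as 16-bit TIFF holding integer camera counts (0..65535).

write_stack_tiff <- function(a, path) {
  if (is.matrix(a)) a <- array(a, dim = c(dim(a), 1L))
  if (any(a < 0) || any(a > 65535) || any(a != round(a)))
    cr_error("stack values must be integer counts in 0..65535 for storage",
             "invalid_stack_values")
  pages <- lapply(seq_len(dim(a)[3]), function(k) a[, , k] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none",
                  reduce = FALSE)
  invisible(path)
}

read_stack_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  a <- array(0, dim = c(dim(pages[[1]]), length(pages)))
  for (k in seq_along(pages)) a[, , k] <- round(pages[[k]] * 65535)
  a
}

#' Central analysis plane of a 3D mask
#'
#' The z index of the 3D object's voxel centroid, rounded to the nearest
#' slice (exact halves round toward the lower z), together with the mask
#' at that slice.
#'
#' @param mask3d binary array `(y, x, z)`.
#' @return list with `z_index` and `mask2d`.
#' @export
central_plane_from_3d <- function(mask3d) {
  stopifnot(length(dim(mask3d)) == 3L)
  idx <- which(mask3d > 0)
  if (length(idx) == 0L) cr_error("empty mask", "empty_mask")
  zc <- mean(arrayInd(idx, dim(mask3d))[, 3])
  z_index <- as.integer(ceiling(zc - 0.5))  # half-ties toward lower z
  list(z_index = z_index, mask2d = (mask3d[, , z_index] > 0) * 1L)
}

#' Write a cohort of scenes to a directory bundle
#'
#' Per scene: `chromatin_<id>.tif`, `nucleolus_<id>.tif`, optional
#' `spots_<id>.tif` (multi-page 16-bit), `mask2d_<id>.tif` and
#' `mask3d_<id>.tif` label masks, and a `truth_<id>.json` sidecar.
#' A bundle-level `annotations.csv` lists nucleus ids, 0-based `(z, y,
#' x)` nucleolus-centre coordinates, condition and tissue; `meta.json`
#' records the voxel pitches.
#'
#' @param scenes a `nucleus_scene` or list thereof.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scene_bundle <- function(scenes, dir) {
  if (inherits(scenes, "nucleus_scene")) scenes <- list(scenes)
  stopifnot(length(scenes) >= 1L)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  rows <- lapply(scenes, function(sc) {
    id <- sc$nucleus_id
    write_stack_tiff(sc$channels$chromatin,
                     file.path(dir, paste0("chromatin_", id, ".tif")))
    write_stack_tiff(sc$channels$nucleolus,
                     file.path(dir, paste0("nucleolus_", id, ".tif")))
    if (!is.null(sc$channels$spots))
      write_stack_tiff(sc$channels$spots,
                       file.path(dir, paste0("spots_", id, ".tif")))
    write_stack_tiff(sc$mask2d, file.path(dir, paste0("mask2d_", id, ".tif")))
    write_stack_tiff(sc$mask3d, file.path(dir, paste0("mask3d_", id, ".tif")))
    truth <- sc$truth
    truth$spot_field <- NULL  # rendered field is not serializable truth
    jsonlite::write_json(truth, file.path(dir, paste0("truth_", id, ".json")),
                         auto_unbox = TRUE, digits = NA)
    data.frame(nucleus_id = id,
               z = sc$nucleolus_center[["z"]] - 1L,
               y = sc$nucleolus_center[["y"]] - 1L,
               x = sc$nucleolus_center[["x"]] - 1L,
               condition = sc$condition, tissue = sc$tissue,
               central_z = sc$central_z - 1L,
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), file.path(dir, "annotations.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(voxel_xy = scenes[[1]]$voxel_xy,
                            voxel_z = scenes[[1]]$voxel_z,
                            coordinate_order = "zyx",
                            coordinate_base = 0),
                       file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Load a scene bundle from disk
#'
#' Reads the stacks, masks, annotations and truth sidecars written by
#' [write_scene_bundle()] and validates them: stack/mask dimensions must
#' agree (`dimension_mismatch`), every nucleus needs an annotation
#' (`missing_annotation`) and the annotation must fall inside the mask
#' (`annotation_outside_mask`). A bundle that ships only a 3D mask gets
#' its 2D mask derived via [central_plane_from_3d()].
#'
#' @param dir bundle directory.
#' @return list of `nucleus_scene` objects.
#' @export
load_scene_bundle <- function(dir) {
  ann_path <- file.path(dir, "annotations.csv")
  if (!file.exists(ann_path))
    cr_error("annotations.csv not found", "missing_annotation")
  ann <- utils::read.csv(ann_path, stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(file.path(dir, "meta.json"))
  lapply(seq_len(nrow(ann)), function(i) {
    id <- ann$nucleus_id[i]
    chrom <- read_stack_tiff(file.path(dir, paste0("chromatin_", id, ".tif")))
    nucl_path <- file.path(dir, paste0("nucleolus_", id, ".tif"))
    nucl <- if (file.exists(nucl_path)) read_stack_tiff(nucl_path) else NULL
    spots_path <- file.path(dir, paste0("spots_", id, ".tif"))
    spots <- if (file.exists(spots_path)) read_stack_tiff(spots_path) else NULL
    m3_path <- file.path(dir, paste0("mask3d_", id, ".tif"))
    m2_path <- file.path(dir, paste0("mask2d_", id, ".tif"))
    mask3d <- if (file.exists(m3_path)) read_stack_tiff(m3_path) else NULL
    for (s in list(nucl, spots, mask3d)) {
      if (!is.null(s) && !identical(dim(s), dim(chrom)))
        cr_error(paste0("dimension mismatch in bundle for ", id),
                 "dimension_mismatch")
    }
    if (file.exists(m2_path)) {
      mask2d <- read_stack_tiff(m2_path)[, , 1]
      central_z <- ann$central_z[i] + 1L
    } else if (!is.null(mask3d)) {
      cp <- central_plane_from_3d(mask3d)
      mask2d <- cp$mask2d
      central_z <- cp$z_index
    } else {
      cr_error(paste0("no mask found for ", id), "dimension_mismatch")
    }
    if (!identical(dim(mask2d), dim(chrom)[1:2]))
      cr_error(paste0("2D mask dimension mismatch for ", id),
               "dimension_mismatch")
    if (any(is.na(c(ann$z[i], ann$y[i], ann$x[i]))))
      cr_error(paste0("missing annotation for ", id), "missing_annotation")
    ctr <- c(y = ann$y[i] + 1L, x = ann$x[i] + 1L, z = ann$z[i] + 1L)
    inside <- if (!is.null(mask3d)) mask3d[ctr["y"], ctr["x"], ctr["z"]] > 0
              else mask2d[ctr["y"], ctr["x"]] > 0
    if (!inside)
      cr_error(paste0("annotation outside mask for ", id),
               "annotation_outside_mask")
    truth_path <- file.path(dir, paste0("truth_", id, ".json"))
    truth <- if (file.exists(truth_path))
      jsonlite::read_json(truth_path, simplifyVector = TRUE) else NULL
    structure(list(channels = list(chromatin = chrom, nucleolus = nucl,
                                   spots = spots),
                   mask2d = mask2d, mask3d = mask3d,
                   nucleolus_center = ctr, central_z = central_z,
                   voxel_xy = meta$voxel_xy, voxel_z = meta$voxel_z,
                   tissue = ann$tissue[i], condition = ann$condition[i],
                   nucleus_id = id, truth = truth, config = NULL),
              class = "nucleus_scene")
  })
}

format_full <- function(x) {
  ifelse(x == round(x), format(x, scientific = FALSE, trim = TRUE),
         formatC(x, digits = 17, format = "g"))
}

#' Write binned profiles as a heat-map matrix CSV
#'
#' One row per nucleus, 20 columns at the bin centres 2.5...97.5%
#' (heat-map matrix form), `format = "long"` instead writes the tidy
#' columns `nucleus_id`, `bin_center`, `intensity`. Values are written
#' with enough digits to round-trip at full double precision; row order
#' is the input order.
#'
#' @param profiles list of `binned_profile`s (non-empty).
#' @param path output CSV path.
#' @param format `"matrix"` (default) or `"long"`.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profiles, path, format = c("matrix", "long")) {
  format <- match.arg(format)
  if (inherits(profiles, "binned_profile")) profiles <- list(profiles)
  if (length(profiles) == 0L) cr_error("no profiles to write", "empty_input")
  ids <- vapply(seq_along(profiles), function(i) {
    id <- profiles[[i]]$nucleus_id
    if (is.null(id)) paste0("nucleus_", i) else id
  }, character(1))
  centers <- profiles[[1]]$centers
  if (format == "matrix") {
    mat <- do.call(rbind, lapply(profiles, function(p) p$intensity))
    df <- data.frame(nucleus_id = ids,
                     apply(mat, 2, format_full),
                     stringsAsFactors = FALSE, check.names = FALSE)
    names(df) <- c("nucleus_id", paste0("bin_", centers))
  } else {
    df <- data.frame(
      nucleus_id = rep(ids, each = length(centers)),
      bin_center = rep(centers, length(ids)),
      intensity = format_full(unlist(lapply(profiles,
                                            function(p) p$intensity))),
      stringsAsFactors = FALSE)
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a matrix-form profile CSV back into binned profiles
#'
#' @param path CSV written by [write_profiles()] (matrix format).
#' @return list of `binned_profile`s.
#' @export
read_profiles <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  centers <- as.numeric(sub("^bin_", "", names(df)[-1]))
  lapply(seq_len(nrow(df)), function(i) {
    intensity <- as.numeric(df[i, -1])
    structure(list(centers = centers, intensity = intensity,
                   n_samples = rep(NA_integer_, length(centers)),
                   normalized = isTRUE(all.equal(max(intensity), 1)),
                   interpolated = rep(FALSE, length(centers)),
                   nucleus_id = df$nucleus_id[i]),
              class = "binned_profile")
  })
}

#' Write a result table as CSV with full numeric precision
#'
#' @param rows non-empty data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(rows, path) {
  if (!is.data.frame(rows) || nrow(rows) == 0L)
    cr_error("no rows to write", "empty_input")
  num <- vapply(rows, is.numeric, logical(1))
  rows[num] <- lapply(rows[num], format_full)
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Analysis configuration
#'
#' Bundles the tunable analysis parameters: bin width (percent, must
#' divide 100), permutation count, significance level, region
#' definitions, ray sampling step, resolvability and classification
#' thresholds, and the seed. Serializable to YAML with
#' [write_analysis_config()] / [read_analysis_config()].
#'
#' @param bin_width bin width in percent (default 5).
#' @param n_perm permutations for profile comparison.
#' @param alpha significance level.
#' @param regions named list of `c(lo, hi)` percent intervals (disjoint).
#' @param ray_step ray sampling step in voxels.
#' @param min_ray_length resolvability filter length (pixels).
#' @param amp_frac classification amplitude threshold.
#' @param combine_method `"fisher"` or `"pearson"`.
#' @param seed integer seed.
#' @return object of class `analysis_config`.
#' @export
analysis_config <- function(bin_width = 5, n_perm = 10000, alpha = 0.05,
                            regions = list("0-30%" = c(0, 30),
                                           "35-65%" = c(35, 65),
                                           "70-100%" = c(70, 100)),
                            ray_step = 0.5, min_ray_length = 9,
                            amp_frac = 0.25,
                            combine_method = "fisher", seed = 1) {
  if (bin_width <= 0 || 100 %% bin_width != 0)
    cr_error("bin width must divide 100%", "invalid_parameter")
  iv <- do.call(rbind, regions)
  if (any(iv[, 1] >= iv[, 2]) || any(iv[, 1] < 0) || any(iv[, 2] > 100))
    cr_error("regions must be sub-intervals of [0, 100]%", "invalid_parameter")
  ord <- order(iv[, 1])
  if (any(iv[ord, 1][-1] < iv[ord, 2][-nrow(iv)]))
    cr_error("regions must be disjoint", "invalid_parameter")
  structure(list(bin_width = bin_width, n_perm = n_perm, alpha = alpha,
                 regions = regions, ray_step = ray_step,
                 min_ray_length = min_ray_length, amp_frac = amp_frac,
                 combine_method = combine_method, seed = seed),
            class = "analysis_config")
}

#' @rdname analysis_config
#' @param config an `analysis_config`.
#' @param path YAML file path.
#' @export
write_analysis_config <- function(config, path) {
  stopifnot(inherits(config, "analysis_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname analysis_config
#' @export
read_analysis_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$regions <- lapply(raw$regions, as.numeric)
  do.call(analysis_config, raw)
}
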