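#' Normalize a volume by an out-of-focus reference region
#'
#' Contrast-enhanced T1 intensities are in arbitrary scanner units; dividing
#' the whole volume by the mean intensity of a reference box placed over an
#' out-of-focus structure puts the background near 1 and makes thresholds and
#' areas comparable across sessions.  Any positive global rescaling of the
#' input cancels exactly.
#'
#' @param vol a [raster_volume()].
#' @param reference_box `list(corner =, size =)` in 1-based voxel indices.
#' @return A normalized `raster_volume`; the reference mean used is attached
#'   as attribute `reference_mean`.
#' @export
normalize_volume <- function(vol, reference_box) {
  stopifnot(inherits(vol, "raster_volume"))
  m <- box_mean(vol$data, reference_box)
  if (!is.finite(m) || m <= 0) {
    stop("reference region mean is not positive; check the reference box")
  }
  out <- raster_volume(vol$data / m, vol$spacing, vol$unit)
  attr(out, "reference_mean") <- m
  out
}

# One sweep of morphological two-phase region competition (Chan-Vese flavour):
# recompute the inside/outside means, reassign each pixel to the nearer mean,
# then regularise the curve with a 3x3 majority (median) smoothing.
acwe_step <- function(img, mask, lambda1 = 1, lambda2 = 1, smooth = TRUE) {
  n_in <- sum(mask)
  if (n_in == 0L || n_in == length(mask)) return(mask)
  c1 <- mean(img[mask])
  c2 <- mean(img[!mask])
  new_mask <- lambda1 * (img - c1)^2 < lambda2 * (img - c2)^2
  if (smooth) {
    k <- matrix(1, 3, 3)
    cnt <- EBImage::filter2(matrix(as.numeric(new_mask), nrow(img)), k,
                            boundary = 0)
    new_mask <- cnt > 4.5
  }
  new_mask
}

# Evolve a contour mask to convergence on one slice.
acwe_evolve <- function(img, init, max_iter = 40L, smooth = TRUE) {
  mask <- init
  for (i in seq_len(max_iter)) {
    new_mask <- acwe_step(img, mask, smooth = smooth)
    if (identical(new_mask, mask)) break
    mask <- new_mask
  }
  mask
}

#' Segment the hyperintense opening slice by slice with active contours
#'
#' On every analysed slice, pixels above `init_threshold` (in normalized
#' units, i.e. multiples of the background) initialise a region contour which
#' is then evolved by morphological two-phase region competition
#' (a Chan-Vese-type active contour: pixels move to the side whose mean
#' intensity they are closer to, with a 3x3 majority smoothing acting as the
#' curvature term).  Slices without supra-threshold pixels yield empty masks.
#'
#' @param norm_vol normalized `raster_volume` (see [normalize_volume()]).
#' @param slab integer vector of slice indices along the third axis to
#'   analyse; default: all slices where the supra-threshold hyperintense
#'   component survives the size filter.
#' @param init_threshold initialisation threshold relative to the normalized
#'   background; must exceed 1.
#' @param min_component smallest supra-threshold component (px) retained in
#'   the initialisation; filters isolated noise voxels so background slices
#'   start (and stay) empty.
#' @param max_iter maximum contour-evolution sweeps per slice.
#' @param smooth logical; apply the curvature-like smoothing each sweep.
#' @return list of class `opening_segmentation`: `per_slice_masks` (logical
#'   matrices), `slice_indices`, `per_slice_area` (mm^2 or um^2 per
#'   `norm_vol$unit`).
#' @export
segment_opening <- function(norm_vol, slab = NULL, init_threshold = 1.3,
                            min_component = 5L, max_iter = 40L, smooth = TRUE) {
  stopifnot(inherits(norm_vol, "raster_volume"),
            length(dim(norm_vol$data)) == 3L)
  if (init_threshold <= 1) {
    stop("init_threshold must exceed 1 (normalized background level)")
  }
  supra <- norm_vol$data > init_threshold
  slice_init <- function(z) {
    init <- supra[, , z]
    if (!any(init) || min_component <= 1L) return(init)
    lab <- EBImage::bwlabel(matrix(as.numeric(init), nrow(init)))
    sizes <- tabulate(as.integer(lab))
    keep <- which(sizes >= min_component)
    matrix(as.integer(lab) %in% keep, nrow(init))
  }
  n_slices <- dim(norm_vol$data)[3]
  inits <- lapply(seq_len(n_slices), slice_init)
  if (is.null(slab)) {
    slab <- which(vapply(inits, any, logical(1)))
    if (length(slab) == 0L) slab <- seq_len(n_slices)
  }
  if (length(slab) == 0L) stop("empty slice slab")
  if (any(slab < 1L | slab > n_slices)) {
    stop("slab indices outside the volume")
  }
  pixel_area <- prod(norm_vol$spacing[1:2])
  masks <- lapply(slab, function(z) {
    init <- inits[[z]]
    if (!any(init)) return(init)
    acwe_evolve(norm_vol$data[, , z], init, max_iter = max_iter, smooth = smooth)
  })
  structure(list(per_slice_masks = masks,
                 slice_indices = as.integer(slab),
                 per_slice_area = vapply(masks, sum, numeric(1)) * pixel_area,
                 init_threshold = init_threshold),
            class = "opening_segmentation")
}

#' Integrate per-slice areas into the opening volume
#'
#' The opening volume is the sum over analysed slices of the segmented
#' in-plane area times the slice thickness (third spacing component), the
#' per-slice-area-times-slab convention of contrast-MRI volumetry.
#'
#' @param seg an `opening_segmentation`.
#' @param voxel_size numeric length-3 spacing (mm) of the segmented volume.
#' @return list of class `opening_volume_result` with `volume` (mm^3),
#'   `n_slices`, `per_slice_area`.
#' @export
opening_volume <- function(seg, voxel_size) {
  stopifnot(inherits(seg, "opening_segmentation"), length(voxel_size) == 3L)
  pixel_area <- prod(voxel_size[1:2])
  areas <- vapply(seg$per_slice_masks, sum, numeric(1)) * pixel_area
  structure(list(volume = sum(areas) * voxel_size[3],
                 n_slices = length(seg$slice_indices),
                 per_slice_area = areas),
            class = "opening_volume_result")
}

#' Full opening volumetry pipeline
#'
#' Convenience wrapper chaining [normalize_volume()], [segment_opening()] and
#' [opening_volume()] with one call, as used for routine weekly quantification.
#'
#' @inheritParams normalize_volume
#' @inheritParams segment_opening
#' @return An `opening_volume_result` with the normalization reference mean
#'   attached as `reference_mean`.
#' @export
measure_opening_volume <- function(vol, reference_box, slab = NULL,
                                   init_threshold = 1.3, max_iter = 40L) {
  norm <- normalize_volume(vol, reference_box)
  seg <- segment_opening(norm, slab = slab, init_threshold = init_threshold,
                         max_iter = max_iter)
  res <- opening_volume(seg, vol$spacing)
  res$reference_mean <- attr(norm, "reference_mean")
  res
}
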