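#' Raster volumes: scalar grids with anisotropic spacing
#'
#' A `raster_volume` is the common carrier for MR volumes, PET volumes and
#' confocal stacks/fields: a 2D or 3D numeric array plus the physical size of
#' one voxel along each array axis.  Spacing is in millimetres for MR/PET and
#' micrometres for microscopy; the unit is carried along so reports can state
#' it, but no conversion is ever performed implicitly.
#'
#' @param data numeric array (2D or 3D; a 2D multichannel image uses a third
#'   axis of length = number of channels with `spacing[3] = NA`).
#' @param spacing numeric vector, physical size of one voxel per array axis.
#' @param unit length unit of `spacing`, `"mm"` or `"um"`.
#' @return An object of class `raster_volume`.
#' @examples
#' v <- raster_volume(array(0, c(4, 4, 4)), spacing = c(1, 1, 1), unit = "mm")
#' voxel_volume(v)
#' @export
raster_volume <- function(data, spacing, unit = c("mm", "um")) {
  unit <- match.arg(unit)
  if (!is.array(data) && !is.matrix(data)) {
    stop("`data` must be a matrix or array")
  }
  nd <- length(dim(data))
  if (nd < 2L || nd > 3L) stop("`data` must be 2D or 3D")
  if (length(spacing) != nd) {
    stop("`spacing` must have one entry per array axis (", nd, ")")
  }
  if (any(!is.na(spacing) & spacing <= 0)) stop("voxel spacing must be positive")
  structure(list(data = data, spacing = as.numeric(spacing), unit = unit),
            class = "raster_volume")
}

#' @export
print.raster_volume <- function(x, ...) {
  cat("<raster_volume> ", paste(dim(x$data), collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = " x "),
      " ", x$unit, "\n", sep = "")
  invisible(x)
}

#' @rdname raster_volume
#' @param vol a `raster_volume`.
#' @export
voxel_volume <- function(vol) {
  stopifnot(inherits(vol, "raster_volume"))
  prod(vol$spacing)
}

#' Read / write raster volumes as NIfTI-1
#'
#' Thin wrappers around \pkg{RNifti}; voxel spacing travels in the `pixdim`
#' header field.
#'
#' @param vol a `raster_volume`.
#' @param path file path (`.nii` or `.nii.gz`).
#' @param unit length unit to attach on read (NIfTI phantom headers written by
#'   this package always use mm).
#' @return `read_volume_nifti` returns a `raster_volume`; `write_volume_nifti`
#'   returns `path` invisibly.
#' @export
write_volume_nifti <- function(vol, path) {
  stopifnot(inherits(vol, "raster_volume"))
  img <- RNifti::asNifti(vol$data)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume_nifti
#' @export
read_volume_nifti <- function(path, unit = "mm") {
  img <- RNifti::readNifti(path)
  raster_volume(as.array(img), spacing = RNifti::pixdim(img)[seq_along(dim(img))],
                unit = unit)
}

#' Write a multichannel confocal field as TIFF
#'
#' Channels are stored as the frames of a greyscale image stack; intensities
#' are written as 32-bit floats so arbitrary dynamic range survives a
#' round-trip.  Pixel size is not representable in the baseline TIFF tags that
#' \pkg{EBImage} writes, so it is the caller's job to carry it (the phantom
#' generators put it in the ground-truth sidecar).
#'
#' @param field a `raster_volume` whose third axis indexes channels.
#' @param path output `.tif` path.
#' @export
write_field_tiff <- function(field, path) {
  stopifnot(inherits(field, "raster_volume"), length(dim(field$data)) == 3L)
  img <- EBImage::Image(field$data, colormode = "Grayscale")
  EBImage::writeImage(img, path, type = "tiff", bits.per.sample = 32L)
  invisible(path)
}

#' @rdname write_field_tiff
#' @param pixel_size pixel edge length in micrometres to attach on read.
#' @export
read_field_tiff <- function(path, pixel_size = 1) {
  img <- EBImage::readImage(path)
  a <- EBImage::imageData(img)
  if (length(dim(a)) == 2L) a <- array(a, c(dim(a), 1L))
  raster_volume(a, spacing = c(pixel_size, pixel_size, NA), unit = "um")
}

# Run `expr` under a fixed RNG state without disturbing the caller's stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  expr
}

# Mean over an axis-aligned box given as list(corner = c(i,j,k), size = c(...)),
# 1-based voxel indices.
box_indices <- function(box, dims) {
  corner <- as.integer(box$corner)
  size <- as.integer(box$size)
  if (length(corner) != length(dims) || length(size) != length(dims)) {
    stop("reference box must have one corner and size entry per axis")
  }
  if (any(size < 1L)) stop("reference box must have positive size")
  if (any(corner < 1L) || any(corner + size - 1L > dims)) {
    stop("reference box does not fit inside the volume")
  }
  lapply(seq_along(dims), function(a) corner[a]:(corner[a] + size[a] - 1L))
}

box_mean <- function(data, box) {
  idx <- box_indices(box, dim(data))
  mean(do.call(`[`, c(list(data), idx, list(drop = FALSE))))
}
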