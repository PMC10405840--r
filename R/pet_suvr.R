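#' Standardized uptake value ratio over a label volume
#'
#' SUVr = mean uptake over the target region divided by mean uptake over the
#' reference region (here the role played by the whole cerebellum), both
#' unweighted voxel means over a caller-supplied integer label volume
#' co-registered with the PET scan.  The ratio is invariant under any global
#' positive rescaling of the PET volume.
#'
#' @param pet `raster_volume` of uptake.
#' @param labels `raster_volume` (or array) of integer region ids, congruent
#'   with `pet`.
#' @param roi_id target region label.
#' @param reference_ids one or more labels pooled as the reference region.
#' @return list of class `suvr_result`: `roi_suvr`, `roi_mean`,
#'   `reference_mean`, `roi_id`, `reference_ids`, voxel counts.
#' @export
compute_suvr <- function(pet, labels, roi_id, reference_ids) {
  stopifnot(inherits(pet, "raster_volume"))
  lab <- if (inherits(labels, "raster_volume")) labels$data else labels
  if (!all(dim(pet$data) == dim(lab))) {
    stop("PET and label volumes must share the same grid")
  }
  roi <- lab == roi_id
  ref <- array(lab, dim(lab)) %in% reference_ids
  if (!any(roi)) stop("target region label ", roi_id, " is empty")
  if (!any(ref)) stop("reference region is empty")
  roi_mean <- mean(pet$data[roi])
  ref_mean <- mean(pet$data[ref])
  if (ref_mean <= 0) stop("reference region mean must be positive")
  structure(list(roi_suvr = roi_mean / ref_mean, roi_mean = roi_mean,
                 reference_mean = ref_mean, roi_id = roi_id,
                 reference_ids = reference_ids,
                 n_roi_voxels = sum(roi), n_reference_voxels = sum(ref)),
            class = "suvr_result")
}

#' Percent SUVr change between timepoints
#'
#' `percent_change = 100 * (followup / baseline - 1)`; a reduction is
#' negative.
#'
#' @param baseline,followup `suvr_result` objects for the same target region.
#' @return list of class `suvr_change`: `percent_change`, `baseline_suvr`,
#'   `followup_suvr`, `roi_id`.
#' @export
suvr_change <- function(baseline, followup) {
  stopifnot(inherits(baseline, "suvr_result"), inherits(followup, "suvr_result"))
  if (!identical(baseline$roi_id, followup$roi_id)) {
    stop("SUVr change requires the same target region at both timepoints")
  }
  structure(list(percent_change = 100 * (followup$roi_suvr / baseline$roi_suvr - 1),
                 baseline_suvr = baseline$roi_suvr,
                 followup_suvr = followup$roi_suvr,
                 roi_id = baseline$roi_id),
            class = "suvr_change")
}

#' @export
print.suvr_result <- function(x, ...) {
  cat("<suvr_result> ROI", x$roi_id, "SUVr =", signif(x$roi_suvr, 6),
      "(reference mean", signif(x$reference_mean, 6), ")\n")
  invisible(x)
}

#' @export
print.suvr_change <- function(x, ...) {
  cat("<suvr_change> ROI", x$roi_id, ":",
      sprintf("%+.2f%%", x$percent_change),
      "(", signif(x$baseline_suvr, 6), "->", signif(x$followup_suvr, 6), ")\n")
  invisible(x)
}
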