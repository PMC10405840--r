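#' Normalize a channel by an out-of-focus region
#'
#' Divides the image by the mean signal of a background ("out-of-focus") box,
#' so plaque contrast is expressed in multiples of the tissue background and a
#' single fixed threshold works across images.
#'
#' @param channel numeric matrix (the amyloid channel).
#' @param out_of_focus_box `list(corner = c(row, col), size = c(nrow, ncol))`.
#' @return Normalized matrix with attribute `reference_mean`.
#' @export
normalize_channel <- function(channel, out_of_focus_box) {
  stopifnot(is.matrix(channel))
  m <- box_mean(channel, out_of_focus_box)
  if (!is.finite(m) || m <= 0) {
    stop("out-of-focus region mean is not positive; check the box")
  }
  out <- channel / m
  attr(out, "reference_mean") <- m
  out
}

#' Detect amyloid plaques on a normalized channel
#'
#' Binarizes at a fixed threshold (in background multiples), labels connected
#' components, drops components smaller than `min_size`, and measures each
#' plaque: area = pixel count x pixel area, equivalent in-plane radius
#' \eqn{r = \sqrt{area/\pi}}, and the volume inferred from that radius as a
#' sphere, \eqn{\frac{4}{3}\pi r^3}.  With `volume_model = "slab"` the volume
#' is instead area x `section_thickness`.
#'
#' @param normalized numeric matrix from [normalize_channel()].
#' @param fixed_threshold binarization threshold (> 1), held fixed across an
#'   analysis.
#' @param min_size minimum component area in px^2.
#' @param pixel_size um per px.
#' @param volume_model `"sphere"` (default) or `"slab"`.
#' @param section_thickness um, used by the slab model only.
#' @return data.frame of class `plaque_records`, one row per plaque:
#'   `label`, `centroid_x`, `centroid_y`, `area_px`, `area_um2`, `radius_um`,
#'   `volume_um3`; the boundary contours are attached as attribute
#'   `boundaries` (list of n x 2 px matrices).
#' @export
detect_plaques <- function(normalized, fixed_threshold = 2, min_size = 20,
                           pixel_size = 1, volume_model = c("sphere", "slab"),
                           section_thickness = 35) {
  volume_model <- match.arg(volume_model)
  stopifnot(is.matrix(normalized), min_size >= 0)
  if (fixed_threshold <= 1) {
    stop("fixed_threshold must exceed 1 (normalized background level)")
  }
  binary <- normalized > fixed_threshold
  empty <- data.frame(label = integer(0), centroid_x = numeric(0),
                      centroid_y = numeric(0), area_px = numeric(0),
                      area_um2 = numeric(0), radius_um = numeric(0),
                      volume_um3 = numeric(0))
  class(empty) <- c("plaque_records", class(empty))
  if (!any(binary)) return(empty)
  lab <- EBImage::bwlabel(matrix(as.numeric(binary), nrow(binary)))
  sizes <- tabulate(as.integer(lab))
  keep <- which(sizes >= max(1, min_size))
  if (length(keep) == 0L) return(empty)
  contours <- EBImage::ocontour(lab)
  pix <- which(lab > 0, arr.ind = TRUE)
  ids <- as.integer(lab[pix])
  area_px <- sizes[keep]
  cy <- tapply(pix[, 1], ids, mean)[as.character(keep)]
  cx <- tapply(pix[, 2], ids, mean)[as.character(keep)]
  area_um2 <- area_px * pixel_size^2
  radius_um <- sqrt(area_um2 / pi)
  volume_um3 <- if (volume_model == "sphere") {
    4 / 3 * pi * radius_um^3
  } else {
    area_um2 * section_thickness
  }
  out <- data.frame(label = keep, centroid_x = as.numeric(cx),
                    centroid_y = as.numeric(cy), area_px = area_px,
                    area_um2 = area_um2, radius_um = radius_um,
                    volume_um3 = volume_um3)
  attr(out, "boundaries") <- contours[keep]
  attr(out, "fixed_threshold") <- fixed_threshold
  class(out) <- c("plaque_records", class(out))
  out
}

#' Group population / volume statistics with percent decreases
#'
#' Summarizes two plaque-record sets (treated group A against reference group
#' B) by population and volume, and reports the percent decreases
#' \eqn{100 (1 - A/B)} used throughout two-group plaque comparisons.
#'
#' @param records_a,records_b `plaque_records` data.frames (A = comparison
#'   group, B = reference group).
#' @return list of class `plaque_group_stats`: per-group `population`,
#'   `total_volume_um3`, `mean_volume_um3`, plus `percent_decrease_population`
#'   and `percent_decrease_volume` (NA with a warning when the reference group
#'   is empty).
#' @export
plaque_group_stats <- function(records_a, records_b) {
  summ <- function(r) {
    list(population = nrow(r),
         total_volume_um3 = sum(r$volume_um3),
         mean_volume_um3 = if (nrow(r)) mean(r$volume_um3) else NA_real_)
  }
  a <- summ(records_a); b <- summ(records_b)
  if (b$population == 0L) {
    warning("reference group is empty; percent decreases undefined")
    pd_pop <- NA_real_; pd_vol <- NA_real_
  } else {
    pd_pop <- 100 * (1 - a$population / b$population)
    pd_vol <- 100 * (1 - a$total_volume_um3 / b$total_volume_um3)
  }
  structure(list(group_a = a, group_b = b,
                 percent_decrease_population = pd_pop,
                 percent_decrease_volume = pd_vol),
            class = "plaque_group_stats")
}

#' @export
print.plaque_group_stats <- function(x, ...) {
  cat("<plaque_group_stats>\n",
      " A: n =", x$group_a$population,
      " total volume =", signif(x$group_a$total_volume_um3, 6), "um^3\n",
      " B: n =", x$group_b$population,
      " total volume =", signif(x$group_b$total_volume_um3, 6), "um^3\n",
      " population decrease:", round(x$percent_decrease_population, 2), "%\n",
      " volume decrease:    ", round(x$percent_decrease_volume, 2), "%\n")
  invisible(x)
}
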