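#' MR phantom specification
#'
#' Describes a 3D T1-like phantom containing one ellipsoidal hyperintense
#' region (the contrast-enhanced opening) on a uniform background, plus a
#' disjoint "out-of-focus" reference box used by the normalization step.
#' All geometry is in physical units (mm); the reference box is in voxels.
#'
#' @param grid_shape integer length-3, voxels per axis.
#' @param voxel_size numeric length-3, mm per voxel per axis.
#' @param opening_center numeric length-3, ellipsoid centre in mm.
#' @param opening_semi_axes numeric length-3, ellipsoid semi-axes in mm
#'   (a sphere when all equal).
#' @param opening_intensity,background_intensity mean intensities (arbitrary
#'   units); the opening must be brighter than the background.
#' @param reference_box `list(corner =, size =)` in 1-based voxel indices.
#' @param noise_sd standard deviation of additive Gaussian noise (clipped at 0).
#' @param seed integer seed for the noise stream, or `NULL`.
#' @return A list of class `mr_phantom_spec`.
#' @export
mr_phantom_spec <- function(grid_shape, voxel_size, opening_center,
                            opening_semi_axes,
                            opening_intensity = 3, background_intensity = 1,
                            reference_box, noise_sd = 0, seed = NULL) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, length(voxel_size) == 3L,
            length(opening_center) == 3L, length(opening_semi_axes) == 3L)
  if (any(voxel_size <= 0)) stop("voxel size must be positive")
  if (any(opening_semi_axes <= 0)) {
    stop("opening semi-axes must be strictly positive (degenerate ellipsoid)")
  }
  extent <- grid_shape * voxel_size
  if (any(opening_center - opening_semi_axes <= 0) ||
      any(opening_center + opening_semi_axes >= extent)) {
    stop("opening must lie strictly inside the grid")
  }
  if (opening_intensity <= background_intensity) {
    stop("opening_intensity must exceed background_intensity")
  }
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  structure(list(grid_shape = grid_shape, voxel_size = as.numeric(voxel_size),
                 opening_center = as.numeric(opening_center),
                 opening_semi_axes = as.numeric(opening_semi_axes),
                 opening_intensity = opening_intensity,
                 background_intensity = background_intensity,
                 reference_box = reference_box,
                 noise_sd = noise_sd, seed = seed),
            class = "mr_phantom_spec")
}

# Logical mask of voxels whose centres fall inside the spec's ellipsoid.
ellipsoid_mask <- function(spec) {
  cs <- lapply(1:3, function(a) {
    ((seq_len(spec$grid_shape[a]) - 0.5) * spec$voxel_size[a] -
       spec$opening_center[a]) / spec$opening_semi_axes[a]
  })
  u2 <- outer(outer(cs[[1]]^2, cs[[2]]^2, `+`), cs[[3]]^2, `+`)
  u2 <= 1
}

#' Generate an MR phantom with known opening volume
#'
#' Voxels whose centres fall inside the ellipsoid get `opening_intensity`,
#' all others `background_intensity`; Gaussian noise with `noise_sd` is added
#' everywhere and the result clipped at zero.  The attached ground truth
#' carries the analytic ellipsoid volume \eqn{\frac{4}{3}\pi abc}.
#'
#' @param spec an [mr_phantom_spec()].
#' @return `list(volume = raster_volume, truth = ground truth list)`; the truth
#'   holds `true_opening_volume` (mm^3) and the rasterized voxel-count volume
#'   `voxelized_volume` for convergence checks.
#' @examples
#' spec <- mr_phantom_spec(c(40, 40, 40), rep(0.2, 3), rep(4, 3), rep(1.5, 3),
#'                         reference_box = list(corner = c(2, 2, 2), size = rep(6, 3)))
#' ph <- make_mr_phantom(spec)
#' ph$truth$true_opening_volume  # (4/3) * pi * 1.5^3
#' @export
make_mr_phantom <- function(spec) {
  stopifnot(inherits(spec, "mr_phantom_spec"))
  inside <- ellipsoid_mask(spec)
  idx <- box_indices(spec$reference_box, spec$grid_shape)
  ref_overlap <- do.call(`[`, c(list(inside), idx, list(drop = FALSE)))
  if (any(ref_overlap)) stop("reference_box must be disjoint from the opening")
  data <- array(spec$background_intensity, spec$grid_shape)
  data[inside] <- spec$opening_intensity
  if (spec$noise_sd > 0) {
    data <- data + with_seed(spec$seed,
                             array(stats::rnorm(length(data), 0, spec$noise_sd),
                                   spec$grid_shape))
    data[data < 0] <- 0
  }
  truth <- list(
    true_opening_volume = 4 / 3 * pi * prod(spec$opening_semi_axes),
    voxelized_volume = sum(inside) * prod(spec$voxel_size),
    opening_mask = inside
  )
  list(volume = raster_volume(data, spec$voxel_size, "mm"), truth = truth)
}

# --- confocal field ---------------------------------------------------------

# Even-odd point-in-polygon test; poly is an n x 2 matrix of (x, y) vertices.
point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

polyline_length <- function(p) {
  if (nrow(p) < 2L) return(0)
  sum(sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2)))
}

#' Confocal field specification
#'
#' Describes a three-channel (nuclei / tau / amyloid) fluorescence field:
#' tau-positive somata with attached processes drawn as polylines, disk-like
#' amyloid plaques, scattered nuclei, an optional polygonal tissue mask, and
#' per-channel gain and noise.  All coordinates are pixels, `(x, y)` with `x`
#' along the image columns; lengths in ground truth are micrometres.
#'
#' @param image_shape integer `c(nrow, ncol)` in pixels.
#' @param pixel_size pixel edge length in micrometres.
#' @param cells list; each cell is `list(center = c(x, y), radius = px,
#'   processes = list of n x 2 polyline matrices in px)`.  Each polyline must
#'   start on its soma boundary.
#' @param plaques list of `list(center = c(x, y), radius = px)`; plaques must be
#'   pairwise separated by at least 2 px of background.
#' @param nuclei list of `list(center = c(x, y), radius = px)` for the nuclei
#'   channel (geometry is explicit so that the seed never affects geometry; see
#'   [scatter_nuclei()]).
#' @param channel_gains named numeric, multiplicative gain per channel.
#' @param noise_sd named numeric, Gaussian noise sd per channel.
#' @param background_level baseline intensity in every channel.
#' @param signal_level intensity of drawn structures before gain.
#' @param process_width rendered process width in px (odd; polylines are drawn
#'   1 px wide then dilated).
#' @param mask_polygon n x 2 matrix of (x, y) vertices, or `NULL` for the whole
#'   image.
#' @param seed integer seed for the noise stream.
#' @export
confocal_field_spec <- function(image_shape, pixel_size = 1,
                                cells = list(), plaques = list(),
                                nuclei = list(),
                                channel_gains = c(nuclei = 1, tau = 1, amyloid = 1),
                                noise_sd = c(nuclei = 2, tau = 2, amyloid = 2),
                                background_level = 10, signal_level = 200,
                                process_width = 3L,
                                mask_polygon = NULL, seed = NULL) {
  image_shape <- as.integer(image_shape)
  stopifnot(length(image_shape) == 2L, pixel_size > 0)
  if (process_width %% 2L != 1L) stop("process_width must be odd")
  spec <- structure(list(image_shape = image_shape, pixel_size = pixel_size,
                         cells = cells, plaques = plaques, nuclei = nuclei,
                         channel_gains = channel_gains, noise_sd = noise_sd,
                         background_level = background_level,
                         signal_level = signal_level,
                         process_width = as.integer(process_width),
                         mask_polygon = mask_polygon, seed = seed),
                    class = "confocal_field_spec")
  validate_confocal_spec(spec)
  spec
}

validate_confocal_spec <- function(spec) {
  h <- spec$image_shape[1]; w <- spec$image_shape[2]
  in_image <- function(xy, margin = 0) {
    all(xy[, 1] >= 1 + margin & xy[, 1] <= w - margin &
          xy[, 2] >= 1 + margin & xy[, 2] <= h - margin)
  }
  in_mask <- function(xy) {
    if (is.null(spec$mask_polygon)) return(TRUE)
    all(point_in_polygon(xy[, 1], xy[, 2], spec$mask_polygon))
  }
  for (cell in spec$cells) {
    ctr <- rbind(cell$center)
    if (!in_image(ctr, margin = cell$radius)) stop("soma leaves the image")
    if (!in_mask(ctr)) stop("soma centre outside mask polygon")
    for (p in cell$processes) {
      p <- as.matrix(p)
      if (nrow(p) < 2L) stop("process polyline needs at least 2 points")
      d0 <- sqrt(sum((p[1, ] - cell$center)^2))
      if (abs(d0 - cell$radius) > 1.5) {
        stop("process polyline must start on its soma boundary")
      }
      if (!in_image(p, margin = 1)) stop("process leaves the image")
      if (!in_mask(p)) stop("process leaves the mask polygon")
    }
  }
  if (length(spec$plaques) > 1L) {
    ctrs <- t(vapply(spec$plaques, function(p) p$center, numeric(2)))
    radii <- vapply(spec$plaques, function(p) p$radius, numeric(1))
    dd <- as.matrix(stats::dist(ctrs))
    sep <- outer(radii, radii, `+`) + 2
    diag(dd) <- Inf
    if (any(dd <= sep)) {
      stop("plaques must be pairwise separated by at least 2 px of background")
    }
  }
  for (p in spec$plaques) {
    if (!in_image(rbind(p$center), margin = p$radius)) stop("plaque leaves the image")
    if (!in_mask(rbind(p$center))) stop("plaque outside mask polygon")
  }
  invisible(spec)
}

# Stamp a filled disk of given value; center is (x, y) in px.
draw_disk <- function(mat, center, radius, value) {
  x0 <- center[1]; y0 <- center[2]
  rows <- max(1L, floor(y0 - radius)):min(nrow(mat), ceiling(y0 + radius))
  cols <- max(1L, floor(x0 - radius)):min(ncol(mat), ceiling(x0 + radius))
  sub <- outer((rows - y0)^2, (cols - x0)^2, `+`) <= radius^2
  block <- mat[rows, cols, drop = FALSE]
  block[sub] <- value
  mat[rows, cols] <- block
  mat
}

# Rasterize a polyline 1 px wide: dense sampling then rounding.
polyline_pixels <- function(p) {
  p <- as.matrix(p)
  pts <- do.call(rbind, lapply(seq_len(nrow(p) - 1L), function(i) {
    a <- p[i, ]; b <- p[i + 1L, ]
    n <- max(2L, ceiling(sqrt(sum((b - a)^2)) * 4))
    t <- seq(0, 1, length.out = n)
    cbind(a[1] + t * (b[1] - a[1]), a[2] + t * (b[2] - a[2]))
  }))
  unique(round(pts))
}

#' Generate a confocal phantom field with ground truth
#'
#' Renders the spec into a three-channel image (channel order nuclei, tau,
#' amyloid).  The tau channel holds filled somata plus processes drawn 1 px
#' wide and dilated to `process_width`; the amyloid channel holds filled
#' disks; the nuclei channel scattered small disks.  Ground truth records, per
#' cell, both the drawn polyline length and the soma-centre-to-endpoint
#' length (polyline + centre-to-start distance), and per plaque the true
#' radius and the sphere volume inferred from it.
#'
#' @param spec a [confocal_field_spec()].
#' @return `list(field = raster_volume (h x w x 3, um), truth = list)`.
#' @export
make_confocal_field <- function(spec) {
  stopifnot(inherits(spec, "confocal_field_spec"))
  validate_confocal_spec(spec)
  h <- spec$image_shape[1]; w <- spec$image_shape[2]
  chan <- function() matrix(spec$background_level, h, w)
  tau <- chan(); amyloid <- chan(); nuclei <- chan()
  half <- (spec$process_width - 1L) / 2L

  cell_truth <- lapply(seq_along(spec$cells), function(i) {
    cell <- spec$cells[[i]]
    tau <<- draw_disk(tau, cell$center, cell$radius, spec$signal_level)
    pl <- vapply(cell$processes, function(p) {
      pix <- polyline_pixels(p)
      for (k in seq_len(nrow(pix))) {
        tau <<- draw_disk(tau, pix[k, ], half, spec$signal_level)
      }
      polyline_length(as.matrix(p)) * spec$pixel_size
    }, numeric(1))
    cl <- vapply(cell$processes, function(p) {
      p <- as.matrix(p)
      (polyline_length(p) + sqrt(sum((p[1, ] - cell$center)^2))) * spec$pixel_size
    }, numeric(1))
    list(cell = i, center = cell$center, radius_px = cell$radius,
         polyline_lengths_um = pl, center_lengths_um = cl)
  })
  for (p in spec$plaques) {
    amyloid <- draw_disk(amyloid, p$center, p$radius, spec$signal_level)
  }
  for (p in spec$nuclei) {
    nuclei <- draw_disk(nuclei, p$center, p$radius, spec$signal_level)
  }

  arr <- array(0, c(h, w, 3L), dimnames = list(NULL, NULL, c("nuclei", "tau", "amyloid")))
  arr[, , "nuclei"] <- nuclei * spec$channel_gains[["nuclei"]]
  arr[, , "tau"] <- tau * spec$channel_gains[["tau"]]
  arr[, , "amyloid"] <- amyloid * spec$channel_gains[["amyloid"]]
  if (any(spec$noise_sd > 0)) {
    arr <- arr + with_seed(spec$seed, {
      n <- array(0, dim(arr), dimnames = dimnames(arr))
      for (ch in dimnames(arr)[[3]]) {
        n[, , ch] <- stats::rnorm(h * w, 0, spec$noise_sd[[ch]])
      }
      n
    })
    arr[arr < 0] <- 0
  }
  pr <- vapply(spec$plaques, function(p) p$radius, numeric(1)) * spec$pixel_size
  truth <- list(
    cells = cell_truth,
    true_process_lengths = lapply(cell_truth, `[[`, "center_lengths_um"),
    true_plaque_count = length(spec$plaques),
    true_plaque_radii_um = pr,
    true_plaque_volumes_um3 = 4 / 3 * pi * pr^3
  )
  list(field = raster_volume(arr, c(spec$pixel_size, spec$pixel_size, NA), "um"),
       truth = truth)
}

#' Deterministically scatter nuclei centres
#'
#' Places `n` non-overlapping small disks uniformly inside a rectangle.  The
#' seed here is part of the geometry description (it belongs in the spec the
#' caller builds), keeping the phantom contract that the field-level noise
#' seed never changes geometry.
#'
#' @param n number of nuclei.
#' @param image_shape `c(nrow, ncol)` in px.
#' @param radius nucleus radius in px.
#' @param seed integer; fixed seed gives a fixed layout.
#' @return list of `list(center, radius)`.
#' @export
scatter_nuclei <- function(n, image_shape, radius = 3, seed = 1) {
  h <- image_shape[1]; w <- image_shape[2]
  with_seed(seed, {
    out <- list(); tries <- 0L
    while (length(out) < n && tries < 50L * n) {
      tries <- tries + 1L
      cand <- c(stats::runif(1, radius + 2, w - radius - 1),
                stats::runif(1, radius + 2, h - radius - 1))
      ok <- all(vapply(out, function(q) {
        sqrt(sum((q$center - cand)^2)) > 2 * radius + 2
      }, logical(1)))
      if (ok) out[[length(out) + 1L]] <- list(center = cand, radius = radius)
    }
    if (length(out) < n) stop("could not place ", n, " nuclei without overlap")
    out
  })
}

#' Single-process tau phantom with prescribed centre-to-endpoint lengths
#'
#' Builds a confocal field with one soma per requested length, each bearing a
#' single straight horizontal process.  The prescribed lengths follow the
#' tracer's convention (soma centre to process endpoint), so each polyline is
#' drawn from the soma boundary with length `L - soma_radius`.
#'
#' @param lengths_um numeric vector of centre-to-endpoint lengths (um).
#' @param pixel_size um per px.
#' @param soma_radius soma radius in px.
#' @param row_pitch vertical spacing between cells in px.
#' @param noise_sd tau-channel noise sd.
#' @param seed noise seed.
#' @return As [make_confocal_field()].
#' @export
tau_length_phantom <- function(lengths_um, pixel_size = 1, soma_radius = 8,
                               row_pitch = 40, noise_sd = 2, seed = NULL) {
  stopifnot(all(lengths_um > soma_radius * pixel_size))
  len_px <- lengths_um / pixel_size
  n <- length(len_px)
  h <- (n + 1L) * row_pitch
  w <- ceiling(max(len_px)) + 4L * soma_radius + 20L
  x0 <- 2 * soma_radius + 5
  cells <- lapply(seq_len(n), function(i) {
    y <- i * row_pitch
    list(center = c(x0, y), radius = soma_radius,
         processes = list(rbind(c(x0 + soma_radius, y),
                                c(x0 + len_px[i], y))))
  })
  spec <- confocal_field_spec(c(h, w), pixel_size = pixel_size, cells = cells,
                              noise_sd = c(nuclei = 0, tau = noise_sd, amyloid = 0),
                              seed = seed)
  make_confocal_field(spec)
}

#' Plaque-counting phantom: n well-separated disks
#'
#' Lays `n` amyloid disks of a common radius on a regular grid with at least
#' 2 px of background between any two, the validity condition of the plaque
#' detector.
#'
#' @param n number of plaques.
#' @param radius plaque radius in px.
#' @param pixel_size um per px.
#' @param pitch grid pitch in px (must exceed `2 * radius + 2`).
#' @param noise_sd amyloid-channel noise sd.
#' @param seed noise seed.
#' @return As [make_confocal_field()].
#' @export
plaque_field_phantom <- function(n, radius = 4, pixel_size = 1,
                                 pitch = 4 * radius + 4, noise_sd = 2,
                                 seed = NULL) {
  stopifnot(n >= 1, pitch > 2 * radius + 2)
  ncol_g <- ceiling(sqrt(n))
  nrow_g <- ceiling(n / ncol_g)
  # golden-ratio sub-pixel offsets keep disk centres off the pixel lattice,
  # as for real objects; exact lattice alignment is a worst case for
  # pixel-count area estimates
  g1 <- (sqrt(5) - 1) / 2
  plaques <- lapply(seq_len(n), function(k) {
    off <- c((k * g1) %% 1, (k * g1^2) %% 1)
    list(center = c(((k - 1) %% ncol_g) * pitch + pitch,
                    ((k - 1) %/% ncol_g) * pitch + pitch) + off,
         radius = radius)
  })
  shape <- c(nrow_g * pitch + pitch, ncol_g * pitch + pitch)
  spec <- confocal_field_spec(shape, pixel_size = pixel_size, plaques = plaques,
                              noise_sd = c(nuclei = 0, tau = 0, amyloid = noise_sd),
                              seed = seed)
  make_confocal_field(spec)
}

# --- PET phantom ------------------------------------------------------------

#' PET phantom specification and generator
#'
#' `pet_phantom_spec` describes a pair of uptake volumes (baseline and
#' follow-up) over a shared integer label volume; each labelled region has a
#' prescribed mean uptake per timepoint.  `make_pet_pair` renders both
#' timepoints; in the noise-free case every region's voxel values equal its
#' prescribed mean exactly, so the ground-truth SUVr (target mean over
#' reference mean) is exact by construction.
#'
#' @param grid_shape integer length-3.
#' @param voxel_size mm per axis (PET slices are typically anisotropic).
#' @param label_volume integer array of region ids, same shape (0 = background).
#' @param regional_means named list with one named numeric vector per
#'   timepoint, e.g. `list(baseline = c("1" = 1.4, "2" = 1), followup = ...)`;
#'   names are label ids, values strictly positive mean uptakes.
#' @param roi_id target region label.
#' @param reference_ids labels pooled as the reference region ("whole
#'   cerebellum" role).
#' @param noise_sd Gaussian noise sd.
#' @param seed noise seed.
#' @export
pet_phantom_spec <- function(grid_shape, voxel_size, label_volume,
                             regional_means, roi_id, reference_ids,
                             noise_sd = 0, seed = NULL) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, length(voxel_size) == 3L,
            all(dim(label_volume) == grid_shape))
  labels_present <- unique(as.integer(label_volume))
  if (!roi_id %in% labels_present) stop("roi_id not present in label volume")
  if (!any(reference_ids %in% labels_present)) {
    stop("no reference label present in label volume")
  }
  for (tp in names(regional_means)) {
    m <- regional_means[[tp]]
    if (any(m <= 0)) stop("regional means must be strictly positive")
  }
  structure(list(grid_shape = grid_shape, voxel_size = as.numeric(voxel_size),
                 label_volume = label_volume, regional_means = regional_means,
                 roi_id = roi_id, reference_ids = reference_ids,
                 noise_sd = noise_sd, seed = seed),
            class = "pet_phantom_spec")
}

#' @rdname pet_phantom_spec
#' @param spec a `pet_phantom_spec`.
#' @param background_uptake uptake assigned to label 0.
#' @return `list(timepoints = named list of raster_volume, labels =
#'   raster_volume, truth = list(true_suvr = named numeric per timepoint))`.
#' @export
make_pet_pair <- function(spec, background_uptake = 0.1) {
  stopifnot(inherits(spec, "pet_phantom_spec"))
  lab <- as.integer(spec$label_volume)
  vols <- with_seed(spec$seed, lapply(spec$regional_means, function(m) {
    data <- array(background_uptake, spec$grid_shape)
    for (id in names(m)) data[lab == as.integer(id)] <- m[[id]]
    if (spec$noise_sd > 0) {
      data <- data + array(stats::rnorm(length(data), 0, spec$noise_sd),
                           spec$grid_shape)
      data[data < 0] <- 0
    }
    raster_volume(data, spec$voxel_size, "mm")
  }))
  truth <- vapply(spec$regional_means, function(m) {
    ref <- mean(m[as.character(spec$reference_ids)], na.rm = TRUE)
    m[[as.character(spec$roi_id)]] / ref
  }, numeric(1))
  list(timepoints = vols,
       labels = raster_volume(array(lab, spec$grid_shape), spec$voxel_size, "mm"),
       truth = list(true_suvr = truth))
}

#' Two-box PET label volume
#'
#' Convenience label builder: a target box (label 1) and a reference box
#' (label 2) inside a background (label 0).
#'
#' @param grid_shape integer length-3.
#' @param target_box,reference_box `list(corner =, size =)` voxel boxes.
#' @return integer array of labels.
#' @export
pet_label_boxes <- function(grid_shape, target_box, reference_box) {
  lab <- array(0L, grid_shape)
  ti <- box_indices(target_box, grid_shape)
  ri <- box_indices(reference_box, grid_shape)
  lab <- do.call(`[<-`, c(list(lab), ti, list(value = 1L)))
  do.call(`[<-`, c(list(lab), ri, list(value = 2L)))
}

# --- direct length samples --------------------------------------------------

#' Build labelled process-length samples without imaging
#'
#' Produces group-labelled length samples for exercising the CDF machinery
#' directly.  Each group is either an explicit numeric vector or a discrete
#' mixture `list(values =, weights =, n =)`, expanded deterministically into a
#' multiset with counts `n * weights` (which must be whole numbers), so exact
#' enumeration probabilities hold by construction.
#'
#' @param groups named list of numeric vectors and/or mixture lists.
#' @return named list of numeric length vectors (um).
#' @examples
#' make_length_samples(list(son = list(values = c(100, 300), weights = c(0.7, 0.3),
#'                                     n = 10),
#'                          sham = 200))
#' @export
make_length_samples <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 1L, !is.null(names(groups)))
  out <- lapply(groups, function(g) {
    if (is.numeric(g)) {
      v <- as.numeric(g)
    } else {
      stopifnot(is.list(g), all(c("values", "weights", "n") %in% names(g)))
      counts <- g$n * g$weights
      if (any(abs(counts - round(counts)) > 1e-8)) {
        stop("mixture weights times n must be whole numbers")
      }
      v <- rep(as.numeric(g$values), times = round(counts))
    }
    if (length(v) == 0L) stop("empty group in length samples")
    if (any(v <= 0)) stop("process lengths must be positive")
    v
  })
  out
}
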