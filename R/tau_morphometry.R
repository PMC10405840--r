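#' Build the hippocampal analysis mask
#'
#' All morphometry is restricted to the tissue of interest.  If a polygon is
#' supplied it takes precedence and is rasterized directly; otherwise the mask
#' is derived automatically from the nuclei channel by Otsu thresholding
#' followed by morphological closing and hole filling, the usual
#' "tissue footprint" rule for dense nuclear counterstains.
#'
#' @param composite `raster_volume` with a channel axis, or an `h x w x c`
#'   array; channel names must include `"nuclei"` for the automatic rule.
#' @param polygon optional n x 2 matrix of (x, y) vertices in px.
#' @param closing_radius closing radius (px) for the automatic rule.
#' @return logical `h x w` matrix.
#' @export
build_hippocampal_mask <- function(composite, polygon = NULL,
                                   closing_radius = 5) {
  arr <- if (inherits(composite, "raster_volume")) composite$data else composite
  stopifnot(length(dim(arr)) == 3L, dim(arr)[3] >= 1L)
  h <- dim(arr)[1]; w <- dim(arr)[2]
  if (!is.null(polygon)) {
    polygon <- as.matrix(polygon)
    px <- rep(seq_len(w), each = h)
    py <- rep(seq_len(h), times = w)
    mask <- matrix(point_in_polygon(px, py, polygon), h, w)
  } else {
    chn <- dimnames(arr)[[3]]
    nuc <- if (!is.null(chn) && "nuclei" %in% chn) arr[, , "nuclei"] else arr[, , 1]
    rng <- range(nuc)
    if (rng[2] <= rng[1]) stop("mask construction failed: blank composite")
    scaled <- (nuc - rng[1]) / (rng[2] - rng[1])
    thr <- EBImage::otsu(EBImage::Image(scaled))
    mask <- scaled > thr
    brush <- EBImage::makeBrush(2L * closing_radius + 1L, shape = "disc")
    mask <- EBImage::closing(matrix(as.numeric(mask), h), brush) > 0.5
    mask <- EBImage::fillHull(matrix(as.numeric(mask), h)) > 0.5
  }
  if (!any(mask)) stop("hippocampal mask is empty")
  mask
}

#' Isolate the highest-intensity tau structures by k-means
#'
#' Clusters the masked pixel intensities into `k` groups and keeps the cluster
#' with the largest mean, the "highest intensities" of the tau stain.
#' Initial centres are placed at fixed intensity quantiles, so the result is
#' deterministic.  When the masked image carries fewer than `k` distinct
#' levels the clustering is degenerate and the operation falls back to
#' thresholding at the top level, with a warning.
#'
#' @param tau numeric matrix, the tau channel.
#' @param mask logical matrix, or `NULL` for the whole image.
#' @param k number of intensity clusters (>= 2).
#' @return logical matrix: pixels in the brightest cluster (FALSE outside the
#'   mask).
#' @export
segment_tau <- function(tau, mask = NULL, k = 3L) {
  stopifnot(is.matrix(tau), k >= 2L)
  if (is.null(mask)) mask <- matrix(TRUE, nrow(tau), ncol(tau))
  vals <- tau[mask]
  ulev <- unique(vals)
  out <- matrix(FALSE, nrow(tau), ncol(tau))
  if (length(ulev) < k) {
    warning("fewer than k distinct intensity levels; thresholding at the top level")
    out[mask] <- vals >= max(vals)
    if (length(ulev) == 1L) out[] <- FALSE  # constant image: nothing stands out
    return(out)
  }
  centers <- stats::quantile(vals, probs = seq(0.05, 0.95, length.out = k),
                             names = FALSE)
  centers <- centers + seq_len(k) * 1e-9  # force distinct init
  km <- stats::kmeans(vals, centers = matrix(centers, ncol = 1),
                      iter.max = 50L, algorithm = "Lloyd")
  top <- which.max(km$centers)
  out[mask] <- km$cluster == top
  out
}

#' Detect circular soma centres with a Hough transform
#'
#' Classic circular Hough voting: boundary pixels of the binary map vote on an
#' annulus accumulator for every candidate radius; the accumulator is
#' normalized by ring size so a complete circle scores 1.  Peaks above
#' `accum_threshold` are kept and merged greedily so no two accepted centres
#' lie closer than the minimum radius.
#'
#' @param map logical/0-1 matrix (typically [segment_tau()] output).
#' @param radius_range `c(min, max)` candidate radii in px.
#' @param accum_threshold minimum fraction of the circle perimeter that must
#'   be present (default 0.5; somata with one or two attached processes lose
#'   only a few perimeter pixels).
#' @param radius_step accumulator radius step in px.
#' @return data.frame with columns `x`, `y`, `radius`, `score`, one row per
#'   detected soma (possibly zero rows).
#' @export
detect_cell_centers <- function(map, radius_range, accum_threshold = 0.5,
                                radius_step = 1) {
  stopifnot(length(radius_range) == 2L, radius_range[1] > 0,
            radius_range[1] < radius_range[2])
  b <- matrix(as.numeric(map > 0), nrow(map), ncol(map))
  if (!any(b > 0)) {
    return(data.frame(x = numeric(0), y = numeric(0), radius = numeric(0),
                      score = numeric(0)))
  }
  inner <- EBImage::filter2(b, matrix(1, 3, 3), boundary = 0) > 8.5
  edge <- b > 0 & !inner
  edge_num <- matrix(as.numeric(edge), nrow(b))
  radii <- seq(radius_range[1], radius_range[2], by = radius_step)
  best <- matrix(0, nrow(b), ncol(b))
  best_r <- matrix(radii[1], nrow(b), ncol(b))
  for (r in radii) {
    sz <- 2L * ceiling(r) + 1L
    ctr <- ceiling(r) + 1L
    d <- sqrt(outer((seq_len(sz) - ctr)^2, (seq_len(sz) - ctr)^2, `+`))
    ring <- matrix(as.numeric(abs(d - r) <= 0.5), sz, sz)
    acc <- EBImage::filter2(edge_num, ring, boundary = 0) / sum(ring)
    upd <- acc > best
    best[upd] <- acc[upd]
    best_r[upd] <- r
  }
  cand <- which(best >= accum_threshold, arr.ind = TRUE)
  if (nrow(cand) == 0L) {
    return(data.frame(x = numeric(0), y = numeric(0), radius = numeric(0),
                      score = numeric(0)))
  }
  sc <- best[cand]
  ord <- order(-sc, cand[, 1], cand[, 2])
  cand <- cand[ord, , drop = FALSE]
  sc <- sc[ord]
  min_sep <- radius_range[1]
  keep <- integer(0)
  for (i in seq_len(nrow(cand))) {
    p <- cand[i, ]
    if (length(keep) == 0L ||
        all((cand[keep, 1] - p[1])^2 + (cand[keep, 2] - p[2])^2 > min_sep^2)) {
      keep <- c(keep, i)
    }
  }
  data.frame(x = cand[keep, 2], y = cand[keep, 1],
             radius = best_r[cand[keep, , drop = FALSE]],
             score = sc[keep])
}

top5_count <- function(n) as.integer(max(1, ceiling(0.05 * n)))

#' Trace soma-to-endpoint geodesic path lengths
#'
#' For every detected centre, the trace starts at the nearest skeleton node
#' within `neighborhood_radius` and follows the skeleton graph to every
#' reachable endpoint; the path length is the geodesic distance along the
#' 8-connected skeleton (axial steps weigh `pixel_size`, diagonal steps
#' `sqrt(2) * pixel_size`).  Endpoints reachable from several centres are
#' assigned to the geodesically nearer one (ties to the smaller centre
#' index).  Per cell, the longest-5% statistic averages the
#' `ceiling(0.05 * n)` largest path lengths (minimum one).
#'
#' @param skel a [skeletonize_processes()] result.
#' @param centers data.frame with `x`, `y` (and optionally `radius`) as from
#'   [detect_cell_centers()].
#' @param neighborhood_radius search radius (px) for the starting node;
#'   default 1.5 x the largest detected soma radius (or 12 px if no radii).
#' @return list of `cell_process_record`: `center`, `start_node`,
#'   `path_lengths` (um), `top5_mean` (um), `flagged` (no skeleton node in the
#'   neighbourhood).
#' @export
trace_processes <- function(skel, centers, neighborhood_radius = NULL) {
  stopifnot(inherits(skel, "skeleton_graph"), nrow(centers) >= 1L)
  if (is.null(neighborhood_radius)) {
    neighborhood_radius <- if (!is.null(centers$radius) && length(centers$radius)) {
      1.5 * max(centers$radius)
    } else 12
  }
  n_cells <- nrow(centers)
  empty_record <- function(i) {
    structure(list(center = c(x = centers$x[i], y = centers$y[i]),
                   start_node = NA_integer_, path_lengths = numeric(0),
                   top5_mean = NA_real_, flagged = TRUE),
              class = "cell_process_record")
  }
  if (nrow(skel$nodes) == 0L) return(lapply(seq_len(n_cells), empty_record))
  starts <- integer(n_cells)
  for (i in seq_len(n_cells)) {
    d2 <- (skel$nodes$x - centers$x[i])^2 + (skel$nodes$y - centers$y[i])^2
    j <- which.min(d2)
    starts[i] <- if (sqrt(d2[j]) <= neighborhood_radius) j else NA_integer_
  }
  live <- which(!is.na(starts))
  ep <- skel$endpoints
  dist_mat <- matrix(Inf, n_cells, length(ep))
  if (length(live) && length(ep)) {
    dist_mat[live, ] <- igraph::distances(skel$graph, v = starts[live], to = ep,
                                          weights = igraph::E(skel$graph)$weight)
  }
  # endpoint -> nearest centre (geodesic), ties to the smaller centre index
  owner <- apply(dist_mat, 2L, function(col) {
    if (all(!is.finite(col))) NA_integer_ else which.min(col)
  })
  lapply(seq_len(n_cells), function(i) {
    if (is.na(starts[i])) return(empty_record(i))
    mine <- which(!is.na(owner) & owner == i)
    pl <- dist_mat[i, mine]
    pl <- pl[is.finite(pl)]
    structure(list(center = c(x = centers$x[i], y = centers$y[i]),
                   start_node = starts[i],
                   path_lengths = sort(pl, decreasing = TRUE),
                   top5_mean = if (length(pl)) {
                     mean(sort(pl, decreasing = TRUE)[seq_len(top5_count(length(pl)))])
                   } else NA_real_,
                   flagged = length(pl) == 0L),
              class = "cell_process_record")
  })
}

#' Per-group length CDF
#'
#' Builds the empirical CDF of the per-cell process-length statistic: by
#' default the longest-5% mean of each cell; `statistic = "pooled"` instead
#' pools every soma-to-endpoint path length.
#'
#' @param records list of `cell_process_record` (one group).
#' @param statistic `"top5_mean"` or `"pooled"`.
#' @return An [empirical_cdf()].
#' @export
length_cdf <- function(records, statistic = c("top5_mean", "pooled")) {
  statistic <- match.arg(statistic)
  vals <- if (statistic == "top5_mean") {
    v <- vapply(records, `[[`, numeric(1), "top5_mean")
    v[!is.na(v)]
  } else {
    unlist(lapply(records, `[[`, "path_lengths"))
  }
  if (length(vals) == 0L) stop("no records with measured path lengths")
  empirical_cdf(vals)
}

#' Monte-Carlo pairwise-difference CDF between two length groups
#'
#' Draws `n_mc` independent pairs, one length from each group's empirical
#' distribution (resampling with replacement), forms the differences
#' \eqn{a - b}, and reports their CDF together with the zero-crossing
#' probability \eqn{P(A < B)} (the fraction of strictly negative
#' differences).  As `n_mc` grows this converges to the exact double-sum
#' \eqn{\sum_{ij} 1[a_i < b_j] / (n_A n_B)}.
#'
#' @param group_a,group_b numeric length samples (um).
#' @param n_mc number of Monte-Carlo pairs.
#' @param seed integer seed.
#' @return list of class `difference_cdf_result`: `diff_cdf`
#'   ([empirical_cdf()] of the differences), `p_A_less_B`, `n_mc`, `seed`.
#' @export
mc_difference_cdf <- function(group_a, group_b, n_mc = 1e5, seed = 1L) {
  stopifnot(length(group_a) >= 1L, length(group_b) >= 1L, n_mc >= 1)
  diffs <- with_seed(seed, {
    a <- group_a[sample.int(length(group_a), n_mc, replace = TRUE)]
    b <- group_b[sample.int(length(group_b), n_mc, replace = TRUE)]
    a - b
  })
  structure(list(diff_cdf = empirical_cdf(diffs),
                 p_A_less_B = mean(diffs < 0),
                 n_mc = as.integer(n_mc), seed = seed),
            class = "difference_cdf_result")
}

#' End-to-end tau process morphometry on one field
#'
#' Chains the structural algorithm: mask, k-means segmentation of the tau
#' channel, Hough soma detection, closing + skeletonization, and geodesic
#' tracing with the longest-5% rule.
#'
#' @param field `raster_volume` with a `"tau"` channel (or an `h x w` tau
#'   matrix).
#' @param pixel_size um per px (taken from the field spacing when available).
#' @param mask_polygon optional polygon for [build_hippocampal_mask()];
#'   `NULL` skips masking when no nuclei channel is present.
#' @param k clusters for [segment_tau()].
#' @param radius_range soma radii (px) for [detect_cell_centers()].
#' @param closing_radius see [skeletonize_processes()].
#' @param neighborhood_radius see [trace_processes()].
#' @return list: `records`, `centers`, `segmented`, `skeleton`.
#' @export
measure_tau_processes <- function(field, pixel_size = NULL, mask_polygon = NULL,
                                  k = 3L, radius_range = c(5, 12),
                                  closing_radius = 2,
                                  neighborhood_radius = NULL) {
  if (inherits(field, "raster_volume")) {
    if (is.null(pixel_size)) pixel_size <- field$spacing[1]
    arr <- field$data
    tau <- if (length(dim(arr)) == 3L) {
      chn <- dimnames(arr)[[3]]
      if (!is.null(chn) && "tau" %in% chn) arr[, , "tau"] else arr[, , 1]
    } else arr
  } else {
    tau <- field
    if (is.null(pixel_size)) pixel_size <- 1
  }
  mask <- if (!is.null(mask_polygon)) {
    build_hippocampal_mask(array(tau, c(dim(tau), 1L)), polygon = mask_polygon)
  } else NULL
  seg <- segment_tau(tau, mask = mask, k = k)
  centers <- detect_cell_centers(seg, radius_range = radius_range)
  skel <- skeletonize_processes(seg, pixel_size = pixel_size,
                                closing_radius = closing_radius)
  records <- if (nrow(centers)) {
    trace_processes(skel, centers, neighborhood_radius = neighborhood_radius)
  } else list()
  list(records = records, centers = centers, segmented = seg, skeleton = skel)
}
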