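# Topological thinning and the skeleton graph.
#
# EBImage supplies the morphological operators used before thinning, but no
# skeletonizer, so the classic two-subiteration thinning of Zhang & Suen is
# implemented here directly, vectorized over the whole image.

# Shift a matrix by (dy, dx), padding with 0.
shift_mat <- function(m, dy, dx) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0L, nr, nc)
  ys <- max(1, 1 + dy):min(nr, nr + dy)
  xs <- max(1, 1 + dx):min(nc, nc + dx)
  out[ys, xs] <- m[ys - dy, xs - dx]
  out
}

# Zhang-Suen thinning of a logical matrix to a 1-px-wide skeleton.
thin_binary <- function(mask) {
  m <- matrix(as.integer(mask), nrow(mask), ncol(mask))
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      # neighbours in the order P2..P9 = N, NE, E, SE, S, SW, W, NW
      p2 <- shift_mat(m, 1, 0);  p3 <- shift_mat(m, 1, -1)
      p4 <- shift_mat(m, 0, -1); p5 <- shift_mat(m, -1, -1)
      p6 <- shift_mat(m, -1, 0); p7 <- shift_mat(m, -1, 1)
      p8 <- shift_mat(m, 0, 1);  p9 <- shift_mat(m, 1, 1)
      b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      a <- (p2 == 0 & p3 == 1) + (p3 == 0 & p4 == 1) + (p4 == 0 & p5 == 1) +
        (p5 == 0 & p6 == 1) + (p6 == 0 & p7 == 1) + (p7 == 0 & p8 == 1) +
        (p8 == 0 & p9 == 1) + (p9 == 0 & p2 == 1)
      if (step == 1) {
        cond <- p2 * p4 * p6 == 0 & p4 * p6 * p8 == 0
      } else {
        cond <- p2 * p4 * p8 == 0 & p2 * p6 * p8 == 0
      }
      del <- m == 1 & b >= 2 & b <= 6 & a == 1 & cond
      if (any(del)) {
        m[del] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m == 1L
}

#' Skeletonize a binary process map into a weighted graph
#'
#' Applies a morphological closing (to bridge small gaps between neighbouring
#' pixels of the same process), thins the result to a 1-px backbone, and
#' builds the 8-connected skeleton graph whose edge weights are the physical
#' step lengths: `pixel_size` for axial steps, `sqrt(2) * pixel_size` for
#' diagonal ones.  Degree-1 nodes are the process endpoints, degree >= 3 nodes
#' the branch points.
#'
#' @param binary logical/0-1 matrix (from [segment_tau()]).
#' @param pixel_size um per px.
#' @param closing_radius radius (px) of the disk used for the closing; 0
#'   disables it.
#' @return list of class `skeleton_graph`: `graph` (igraph, weighted), `nodes`
#'   (data.frame x, y), `endpoints`, `branchpoints` (node indices),
#'   `skeleton` (logical matrix), `pixel_size`.
#' @export
skeletonize_processes <- function(binary, pixel_size = 1, closing_radius = 2) {
  mask <- binary > 0
  if (closing_radius > 0 && any(mask)) {
    brush <- EBImage::makeBrush(2L * closing_radius + 1L, shape = "disc")
    mask <- EBImage::closing(matrix(as.numeric(mask), nrow(mask)), brush) > 0.5
  }
  skel <- if (any(mask)) thin_binary(mask) else mask
  pix <- which(skel, arr.ind = TRUE)  # row = y, col = x
  n <- nrow(pix)
  if (n == 0L) {
    g <- igraph::make_empty_graph(0, directed = FALSE)
    return(structure(list(graph = g,
                          nodes = data.frame(x = numeric(0), y = numeric(0)),
                          endpoints = integer(0), branchpoints = integer(0),
                          skeleton = skel, pixel_size = pixel_size),
                     class = "skeleton_graph"))
  }
  id <- matrix(0L, nrow(skel), ncol(skel))
  id[pix] <- seq_len(n)
  offsets <- list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))  # E, S, SE, SW
  edges <- list(); weights <- list()
  for (k in seq_along(offsets)) {
    off <- offsets[[k]]
    ny <- pix[, 1] + off[1]; nx <- pix[, 2] + off[2]
    ok <- ny >= 1 & ny <= nrow(skel) & nx >= 1 & nx <= ncol(skel)
    nb <- rep(0L, n)
    nb[ok] <- id[cbind(ny[ok], nx[ok])]
    has <- nb > 0L
    if (any(has)) {
      edges[[k]] <- rbind(seq_len(n)[has], nb[has])
      weights[[k]] <- rep(if (all(off != 0)) sqrt(2) else 1, sum(has)) * pixel_size
    }
  }
  el <- if (length(edges)) t(do.call(cbind, edges)) else matrix(0L, 0, 2)
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(el)) {
    g <- igraph::add_edges(g, t(el))
    igraph::E(g)$weight <- unlist(weights)
  }
  deg <- igraph::degree(g)
  structure(list(graph = g,
                 nodes = data.frame(x = pix[, 2], y = pix[, 1]),
                 endpoints = which(deg == 1L),
                 branchpoints = which(deg >= 3L),
                 skeleton = skel, pixel_size = pixel_size),
            class = "skeleton_graph")
}

#' @export
print.skeleton_graph <- function(x, ...) {
  cat("<skeleton_graph>", nrow(x$nodes), "nodes,",
      length(x$endpoints), "endpoints,",
      length(x$branchpoints), "branchpoints\n")
  invisible(x)
}
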