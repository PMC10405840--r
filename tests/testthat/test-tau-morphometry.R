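test_that("a supplied polygon overrides the automatic mask rule", {
  arr <- array(0, c(40, 50, 1))
  poly <- rbind(c(10, 5), c(30, 5), c(30, 25), c(10, 25))  # (x, y) rectangle
  mask <- build_hippocampal_mask(arr, polygon = poly)
  expect_equal(dim(mask), c(40, 50))
  # interior in, exterior out (vertices/edges may fall either way)
  expect_true(mask[10, 20])
  expect_false(mask[30, 40])
  expect_equal(sum(mask), sum(outer(1:40, 1:50, function(y, x)
    x > 10 & x <= 30 & y > 5 & y <= 25)))
})

test_that("the automatic mask covers a nuclei-filled disk and rejects blanks", {
  h <- 80; w <- 80
  nuc <- matrix(5, h, w)
  for (dx in seq(-18, 18, by = 6)) for (dy in seq(-18, 18, by = 6)) {
    if (dx^2 + dy^2 <= 18^2) {
      nuc <- sonoquant:::draw_disk(nuc, c(40 + dx, 40 + dy), 3, 200)
    }
  }
  arr <- array(nuc, c(h, w, 1), dimnames = list(NULL, NULL, "nuclei"))
  mask <- build_hippocampal_mask(arr, closing_radius = 6)
  disk <- outer((1:h - 40)^2, (1:w - 40)^2, `+`) <= 15^2
  expect_gt(sum(mask & disk) / sum(disk), 0.95)
  expect_error(build_hippocampal_mask(array(1, c(20, 20, 1))), "blank")
})

test_that("k-means segmentation isolates the brightest cluster", {
  set.seed(1)
  img <- matrix(10, 50, 50)
  img[20:30, 10:40] <- 200
  seg <- segment_tau(img + matrix(rnorm(2500, 0, 1), 50), k = 2)
  expect_equal(unname(seg[25, 25]), TRUE)
  expect_equal(sum(seg), 11 * 31)
  # three constructed levels, k = 3: top cluster only
  img3 <- matrix(10, 50, 50)
  img3[5:15, 5:45] <- 90   # halo level
  img3[30:40, 5:45] <- 200 # signal level
  seg3 <- segment_tau(img3 + matrix(rnorm(2500, 0, 1), 50), k = 3)
  expect_true(all(seg3[30:40, 5:45]))
  expect_false(any(seg3[5:15, 5:45]))
  # constant image: degenerate clustering falls back, selecting nothing
  expect_warning(seg0 <- segment_tau(matrix(7, 20, 20), k = 3), "distinct")
  expect_false(any(seg0))
})

test_that("Hough transform finds isolated somata within 2 px and ignores blanks", {
  img <- matrix(0, 80, 120)
  img <- sonoquant:::draw_disk(img, c(30, 40), 8, 1)
  img <- sonoquant:::draw_disk(img, c(90, 30), 10, 1)
  ctrs <- detect_cell_centers(img, radius_range = c(5, 12))
  expect_equal(nrow(ctrs), 2)
  found <- function(x, y) min(sqrt((ctrs$x - x)^2 + (ctrs$y - y)^2))
  expect_lt(found(30, 40), 2)
  expect_lt(found(90, 30), 2)
  expect_equal(nrow(detect_cell_centers(matrix(0, 30, 30), c(5, 12))), 0)
})

test_that("skeletonization yields the expected endpoints and branch points", {
  # 3-px-wide straight bar -> one path with two endpoints
  bar <- matrix(FALSE, 30, 120)
  bar[14:16, 10:109] <- TRUE
  sk <- skeletonize_processes(bar, pixel_size = 1)
  expect_length(sk$endpoints, 2)
  expect_length(sk$branchpoints, 0)
  d <- igraph::distances(sk$graph, v = sk$endpoints[1], to = sk$endpoints[2],
                         weights = igraph::E(sk$graph)$weight)
  expect_lt(abs(d[1] - 99), 5)  # square bar ends erode slightly under thinning
  # T-shaped union -> 3 endpoints, >= 1 branch point
  tee <- matrix(FALSE, 60, 60)
  tee[29:31, 10:50] <- TRUE
  tee[10:29, 29:31] <- TRUE
  skt <- skeletonize_processes(tee, pixel_size = 1)
  expect_length(skt$endpoints, 3)
  expect_gte(length(skt$branchpoints), 1)
  # isolated specks smaller than the closing radius add no endpoints
  sp <- matrix(FALSE, 40, 40)
  sp[20, 20] <- TRUE; sp[5:6, 5:6] <- TRUE
  sks <- skeletonize_processes(sp, pixel_size = 1, closing_radius = 2)
  expect_length(sks$endpoints, 0)
})

test_that("tracing recovers a drawn straight process within 2 um", {
  cell <- list(center = c(20, 25), radius = 8,
               processes = list(rbind(c(28, 25), c(120, 25))))
  spec <- confocal_field_spec(c(50, 150), cells = list(cell),
                              noise_sd = c(nuclei = 0, tau = 2, amyloid = 0),
                              seed = 2)
  ph <- make_confocal_field(spec)
  res <- measure_tau_processes(ph$field)
  expect_equal(nrow(res$centers), 1)
  rec <- res$records[[1]]
  truth <- ph$truth$cells[[1]]$center_lengths_um  # 100 + radius
  expect_equal(length(rec$path_lengths) >= 1, TRUE)
  expect_lt(abs(rec$top5_mean - truth), 2)
})

test_that("the longest-5% rule averages ceiling(0.05 n) paths for n = 1..100", {
  for (n in 1:100) {
    expect_equal(sonoquant:::top5_count(n), max(1, ceiling(0.05 * n)))
  }
  # exercised through tracing arithmetic: 40 paths -> mean of the 2 longest
  rec <- structure(list(path_lengths = sort(1:40, decreasing = TRUE)), class = "cell_process_record")
  k <- sonoquant:::top5_count(40)
  expect_equal(k, 2)
  expect_equal(mean(sort(rec$path_lengths, decreasing = TRUE)[1:k]), 39.5)
})

test_that("disconnected cells never exchange endpoints", {
  cells <- list(
    list(center = c(20, 20), radius = 6,
         processes = list(rbind(c(26, 20), c(80, 20)))),
    list(center = c(20, 80), radius = 6,
         processes = list(rbind(c(26, 80), c(100, 80)))))
  spec <- confocal_field_spec(c(110, 120), cells = cells,
                              noise_sd = c(nuclei = 0, tau = 2, amyloid = 0),
                              seed = 6)
  ph <- make_confocal_field(spec)
  res <- measure_tau_processes(ph$field, radius_range = c(4, 9))
  expect_equal(nrow(res$centers), 2)
  for (rec in res$records) {
    expect_false(rec$flagged)
    # each cell sees only its own process: all its paths < its truth + slack
    expect_lt(max(rec$path_lengths), 100 + 10)
  }
  # a centre far from any skeleton is flagged with empty lengths
  far <- data.frame(x = 110, y = 105, radius = 6)
  rec_far <- trace_processes(res$skeleton, far, neighborhood_radius = 5)[[1]]
  expect_true(rec_far$flagged)
  expect_length(rec_far$path_lengths, 0)
})

test_that("group CDF uses the per-cell longest-5% statistic", {
  mk <- function(v) structure(list(path_lengths = v, top5_mean = max(v), flagged = FALSE),
                              class = "cell_process_record")
  recs <- lapply(c(100, 200, 300), mk)
  cdf <- length_cdf(recs)
  expect_equal(cdf$sorted_values, c(100, 200, 300))
  pooled <- length_cdf(lapply(list(c(10, 100)), mk), statistic = "pooled")
  expect_equal(pooled$n, 2)
  expect_error(length_cdf(list()), "no records")
})

test_that("MC difference CDF matches exact enumeration within 3 standard errors", {
  s <- make_length_samples(list(a = list(values = c(100, 300), weights = c(0.7, 0.3), n = 10),
                                b = c(150, 250)))
  p_exact <- enumerate_p_less(s$a, s$b)
  n_mc <- 2e4
  se <- sqrt(p_exact * (1 - p_exact) / n_mc)
  for (seed in 1:10) {
    res <- mc_difference_cdf(s$a, s$b, n_mc = n_mc, seed = seed)
    expect_lt(abs(res$p_A_less_B - p_exact), 3 * se)
  }
})

test_that("MC difference CDF is symmetric and handles degenerate groups", {
  a <- c(100, 200, 300)
  r1 <- mc_difference_cdf(a, a, n_mc = 5e4, seed = 1)
  r2 <- mc_difference_cdf(a, a, n_mc = 5e4, seed = 2)
  # P(A<B) and P(B<A) agree within MC error when the groups are identical
  p_ba <- 1 - cdf_eval(r2$diff_cdf, 0)  # strictly positive differences
  expect_lt(abs(r1$p_A_less_B - p_ba), 0.01)
  expect_equal(mc_difference_cdf(1, 2, n_mc = 1e3, seed = 1)$p_A_less_B, 1)
  # reproducible for a fixed seed
  expect_identical(mc_difference_cdf(a, a + 10, n_mc = 1e3, seed = 9),
                   mc_difference_cdf(a, a + 10, n_mc = 1e3, seed = 9))
})
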