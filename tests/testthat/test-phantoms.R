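test_that("MR phantom carries the analytic ellipsoid volume and converges on refinement", {
  sp <- small_sphere_spec(radius = 1.5, spacing = 0.1)
  ph <- make_mr_phantom(sp)
  expect_equal(ph$truth$true_opening_volume, 4 / 3 * pi * 1.5^3)
  # voxel-count volume approaches the analytic value as spacing shrinks
  err <- vapply(c(0.2, 0.05), function(s) {
    p <- make_mr_phantom(small_sphere_spec(radius = 1.5, spacing = s))
    abs(p$truth$voxelized_volume / p$truth$true_opening_volume - 1)
  }, numeric(1))
  expect_lt(err[2], err[1])
  expect_lt(err[2], 0.01)  # < 1% at 0.05 mm isotropic
})

test_that("MR phantom geometry is seed-independent; only the noise changes", {
  s1 <- small_sphere_spec(noise_sd = 0.1, seed = 1)
  s2 <- small_sphere_spec(noise_sd = 0.1, seed = 2)
  p1 <- make_mr_phantom(s1); p2 <- make_mr_phantom(s2)
  expect_identical(p1$truth$true_opening_volume, p2$truth$true_opening_volume)
  expect_identical(p1$truth$opening_mask, p2$truth$opening_mask)
  expect_false(identical(p1$volume$data, p2$volume$data))
  # same seed => bit-identical phantom
  expect_identical(make_mr_phantom(s1)$volume$data, p1$volume$data)
})

test_that("MR phantom specs reject degenerate or out-of-grid geometry", {
  expect_error(mr_phantom_spec(c(40, 40, 40), rep(0.1, 3), rep(2, 3), c(0, 0, 0),
                               reference_box = list(corner = rep(2, 3), size = rep(4, 3))),
               "strictly positive")
  expect_error(mr_phantom_spec(c(40, 40, 40), rep(0.1, 3), rep(2, 3), rep(3, 3),
                               reference_box = list(corner = rep(2, 3), size = rep(4, 3))),
               "inside the grid")
  expect_error(mr_phantom_spec(c(40, 40, 40), c(0.1, 0.1, -1), rep(2, 3), rep(1, 3),
                               reference_box = list(corner = rep(2, 3), size = rep(4, 3))),
               "positive")
  # reference box overlapping the opening is rejected at generation time
  sp <- mr_phantom_spec(c(40, 40, 40), rep(0.1, 3), rep(2, 3), rep(1, 3),
                        reference_box = list(corner = rep(18, 3), size = rep(6, 3)))
  expect_error(make_mr_phantom(sp), "disjoint")
})

test_that("confocal ground truth matches the drawn geometry exactly", {
  # one soma, one horizontal 100 px process at 1 um/px
  cell <- list(center = c(20, 30), radius = 8,
               processes = list(rbind(c(28, 30), c(128, 30))))
  spec <- confocal_field_spec(c(60, 160), cells = list(cell),
                              noise_sd = c(nuclei = 0, tau = 0, amyloid = 0))
  ph <- make_confocal_field(spec)
  expect_equal(ph$truth$cells[[1]]$polyline_lengths_um, 100)
  expect_equal(ph$truth$cells[[1]]$center_lengths_um, 108)  # + soma radius
  # plaque count is bijective with drawn disks
  ph72 <- plaque_field_phantom(72, radius = 4, noise_sd = 0)
  expect_equal(ph72$truth$true_plaque_count, 72)
  expect_length(ph72$truth$true_plaque_radii_um, 72)
})

test_that("the 21-cell length ladder has 20th order statistic 620 um", {
  lengths <- c(145 + 25 * (0:19), 900)
  ph <- tau_length_phantom(lengths, noise_sd = 0)
  truth <- sort(unlist(ph$truth$true_process_lengths))
  expect_equal(truth[20], 620)
  expect_equal(cdf_quantile(empirical_cdf(truth), 0.95), 620)
})

test_that("confocal specs reject invalid geometry", {
  # process not starting on the soma boundary
  bad <- list(center = c(20, 20), radius = 8,
              processes = list(rbind(c(40, 20), c(60, 20))))
  expect_error(confocal_field_spec(c(60, 100), cells = list(bad)), "boundary")
  # process leaving the image
  off <- list(center = c(20, 20), radius = 8,
              processes = list(rbind(c(28, 20), c(300, 20))))
  expect_error(confocal_field_spec(c(60, 100), cells = list(off)), "leaves")
  # overlapping plaques violate the separability invariant
  expect_error(confocal_field_spec(c(60, 100),
                                   plaques = list(list(center = c(30, 30), radius = 5),
                                                  list(center = c(36, 30), radius = 5))),
               "separated")
})

test_that("confocal noise is seeded and geometry-independent", {
  mk <- function(seed) tau_length_phantom(c(100, 150), noise_sd = 3, seed = seed)
  a <- mk(5); b <- mk(5); c <- mk(6)
  expect_identical(a$field$data, b$field$data)
  expect_false(identical(a$field$data, c$field$data))
  expect_identical(a$truth$true_process_lengths, c$truth$true_process_lengths)
})

test_that("PET phantom means and ground-truth SUVr are exact when noise-free", {
  lab <- pet_label_boxes(c(16, 16, 8), list(corner = c(3, 3, 2), size = c(5, 5, 4)),
                         list(corner = c(10, 10, 2), size = c(5, 5, 4)))
  spec <- pet_phantom_spec(c(16, 16, 8), c(1, 1, 4), lab,
                           list(baseline = c("1" = 1.4, "2" = 1.0)),
                           roi_id = 1, reference_ids = 2)
  pp <- make_pet_pair(spec)
  expect_equal(mean(pp$timepoints$baseline$data[lab == 1L]), 1.4)
  expect_equal(pp$truth$true_suvr[["baseline"]], 1.4)
  # scaling both regions by 10 leaves the true SUVr unchanged
  spec10 <- pet_phantom_spec(c(16, 16, 8), c(1, 1, 4), lab,
                             list(baseline = c("1" = 14, "2" = 10)),
                             roi_id = 1, reference_ids = 2)
  expect_equal(make_pet_pair(spec10)$truth$true_suvr[["baseline"]], 1.4)
  # missing reference label is rejected
  expect_error(pet_phantom_spec(c(16, 16, 8), c(1, 1, 4), lab,
                                list(baseline = c("1" = 1.4)),
                                roi_id = 1, reference_ids = 7),
               "reference")
})

test_that("length samples expand mixtures deterministically with exact proportions", {
  s <- make_length_samples(list(son = list(values = c(100, 300),
                                           weights = c(0.7, 0.3), n = 10),
                                sham = 200))
  expect_equal(sort(s$son), c(rep(100, 7), rep(300, 3)))
  expect_equal(enumerate_p_less(s$son, s$sham), 0.70)
  expect_error(make_length_samples(list(a = numeric(0))), "empty")
  expect_error(make_length_samples(list(a = c(-1, 2))), "positive")
})
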