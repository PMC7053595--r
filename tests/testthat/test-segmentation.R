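test_that("median subtraction matches the explicit neighborhood oracle", {
  set.seed(31)
  for (i in 1:60) {
    nr <- sample(8:14, 1); nc <- sample(8:14, 1)
    r <- sample(1:3, 1)
    m <- matrix(sample(0:255, nr * nc, replace = TRUE) + 0, nr, nc)
    got <- median_subtract(calibrated_image(m, 100), r)
    expect_equal(unclass(got)[, ], pmax(m - oracle_disk_median(m, r), 0),
                 ignore_attr = TRUE)
  }
  # non-integer intensities take the generic filter path; same contract
  for (i in 1:40) {
    m <- matrix(runif(10 * 10, 0, 50), 10, 10)
    r <- sample(1:3, 1)
    got <- median_subtract(calibrated_image(m, 100), r)
    expect_equal(unclass(got)[, ], pmax(m - oracle_disk_median(m, r), 0),
                 ignore_attr = TRUE)
  }
})

test_that("median subtraction handles constant and single-spike images", {
  flat <- calibrated_image(matrix(17, 9, 9), 100)
  expect_true(all(median_subtract(flat, 2) == 0))

  m <- matrix(10, 11, 11); m[6, 6] <- 100
  out <- median_subtract(calibrated_image(m, 100), 3)
  expect_equal(out[6, 6], 90)
  expect_true(all(out[-(6 + 11 * 5)] == 0))
})

test_that("median subtraction is bounded by the original and by zero", {
  set.seed(32)
  for (i in 1:20) {
    im <- random_image(15, 15)
    out <- median_subtract(im, sample(1:4, 1))
    expect_true(all(out >= 0))
    expect_true(all(out <= unclass(im)))
    expect_equal(attr(out, "pixel_size_nm"), attr(im, "pixel_size_nm"))
  }
  expect_error(median_subtract(random_image(10, 10), 0), ">= 1")
  expect_error(median_subtract(random_image(10, 10), 8), "half the image")
})

test_that("automatic threshold maximizes between-class variance (exhaustive check)", {
  set.seed(33)
  # clearly bimodal 8-bit histogram
  v <- c(rnorm(400, 20, 5), rnorm(200, 200, 10))
  v <- pmin(pmax(round(v), 0), 255)
  im <- calibrated_image(matrix(v, 30, 20), 100)
  expect_equal(otsu_threshold(im), oracle_otsu(v))
  thr <- otsu_threshold(im)
  expect_gt(thr, 30); expect_lt(thr, 190)

  for (i in 1:100) {
    v <- sample(0:255, 120, replace = TRUE)
    expect_equal(otsu_threshold(v), oracle_otsu(v))
  }
})

test_that("binarize respects the strict > rule and degenerate thresholds", {
  im <- calibrated_image(matrix(c(1, 2, 3, 4), 2, 2), 100)
  expect_true(all(binarize(im, 0)))
  expect_false(any(binarize(im, 4)))   # above the maximum -> empty
  expect_false(any(binarize(im, 99)))
  m <- binarize(im, 2)
  expect_equal(sum(m), 2)              # strictly greater than 2
  expect_equal(attr(m, "threshold_used"), 2)
  expect_warning(b <- binarize(calibrated_image(matrix(5, 3, 3), 100), "auto"),
                 "constant")
  expect_false(any(b))
})

test_that("raising the threshold never increases foreground", {
  set.seed(34)
  for (i in 1:20) {
    im <- random_image(12, 12)
    t1 <- runif(1, 0, 200); t2 <- t1 + runif(1, 0, 55)
    expect_lte(sum(binarize(im, t2)), sum(binarize(im, t1)))
  }
})

test_that("connected components match a flood-fill oracle for both connectivities", {
  set.seed(35)
  for (i in 1:60) {
    m <- matrix(runif(32 * 32) < runif(1, 0.2, 0.6), 32, 32)
    for (conn in c(4L, 8L)) {
      got <- label_particles(mask_of(m), min_area_nm2 = 0, connectivity = conn)
      expect_equal(got$labels, oracle_label(m, conn))
    }
  }
})

test_that("area filter is strictly greater-than at the calibrated threshold", {
  # components of 1, 2 and 5 pixels at 100 nm/px: 10000, 20000, 50000 nm^2
  m <- matrix(FALSE, 16, 16)
  m[2, 2] <- TRUE                       # 1 px
  m[5, 5] <- TRUE; m[5, 6] <- TRUE      # 2 px = exactly 20000 nm^2
  m[10, 10:12] <- TRUE; m[11, 10:11] <- TRUE  # 5 px
  vs <- label_particles(mask_of(m, 100), min_area_nm2 = 20000)
  expect_equal(nrow(vs$table), 1)
  expect_equal(vs$table$n_px, 5)
  expect_equal(vs$table$area_nm2, 50000)
})

test_that("diagonal neighbors join under 8- but not 4-connectivity", {
  m <- matrix(FALSE, 4, 4); m[2, 2] <- TRUE; m[3, 3] <- TRUE
  expect_equal(nrow(label_particles(mask_of(m), 0, 8L)$table), 1)
  expect_equal(nrow(label_particles(mask_of(m), 0, 4L)$table), 2)
  empty <- label_particles(mask_of(matrix(FALSE, 8, 8)), 20000)
  expect_equal(nrow(empty$table), 0)
})

test_that("labels are assigned in raster-scan order of first pixel", {
  m <- matrix(FALSE, 6, 6)
  m[5, 1] <- TRUE   # later in raster order (row-wise) than [1, 5]
  m[1, 5] <- TRUE
  vs <- label_particles(mask_of(m), 0)
  expect_equal(vs$labels[1, 5], 1L)
  expect_equal(vs$labels[5, 1], 2L)
})

test_that("increasing min_area never increases the object count", {
  set.seed(36)
  for (i in 1:20) {
    m <- matrix(runif(24 * 24) < 0.4, 24, 24)
    areas <- sort(runif(2, 0, 8e4))
    n1 <- nrow(label_particles(mask_of(m), areas[1])$table)
    n2 <- nrow(label_particles(mask_of(m), areas[2])$table)
    expect_lte(n2, n1)
  }
})

test_that("halving the pixel size quarters every object area", {
  set.seed(37)
  m <- matrix(runif(20 * 20) < 0.3, 20, 20)
  a1 <- label_particles(mask_of(m, 100), 0)$table$area_nm2
  a2 <- label_particles(mask_of(m, 50), 0)$table$area_nm2
  expect_equal(a2, a1 / 4)
})

test_that("integral density is the sum of source intensities over the ROI", {
  im <- calibrated_image(matrix(0, 8, 8), 100)
  im[3, 3] <- 10; im[3, 4] <- 20; im[3, 5] <- 30
  m <- matrix(FALSE, 8, 8); m[3, 3:5] <- TRUE
  vs <- measure_vesicles(im, label_particles(mask_of(m), 0))
  expect_equal(vs$table$integral_density, 60)
  expect_equal(vs$table$mean_intensity, 20)
  expect_equal(vs$table$centroid_row, 3)
  expect_equal(vs$table$centroid_col, 4)

  zero <- calibrated_image(matrix(0, 8, 8), 100)
  expect_equal(measure_vesicles(zero, label_particles(mask_of(m), 0))$table$integral_density, 0)
  expect_error(measure_vesicles(calibrated_image(matrix(0, 5, 5), 100),
                                label_particles(mask_of(m), 0)), "shape")
})

test_that("densities match per-pixel loop summation on random ROIs", {
  set.seed(38)
  for (i in 1:20) {
    im <- random_image(16, 16)
    m <- matrix(runif(16 * 16) < 0.25, 16, 16)
    vs <- measure_vesicles(im, label_particles(mask_of(m), 0))
    lab <- vs$labels
    for (l in vs$table$label) {
      acc <- 0
      for (r in 1:16) for (c in 1:16) if (lab[r, c] == l) acc <- acc + im[r, c]
      expect_equal(vs$table$integral_density[vs$table$label == l], acc)
    }
  }
})

test_that("cell counting works from label images and nuclei channels", {
  cm <- matrix(0L, 10, 10); cm[1:3, 1:3] <- 1L; cm[6:8, 6:8] <- 2L; cm[1, 9] <- 5L
  expect_equal(count_cells(cell_masks = cm), 3)
  expect_warning(n0 <- count_cells(nuclei_image = calibrated_image(matrix(0, 20, 20), 100)))
  expect_equal(n0, 0)
  expect_error(count_cells(), "supply")

  # simulated field at defaults has 4 ground-truth nuclei
  sim <- simulate_field(sim_params(seed = 7))
  nuc <- max_intensity_projection(sim$stack, "nuclei", 1, "all")
  expect_equal(count_cells(nuclei_image = nuc), 4)
})

test_that("segment_channel detects well-separated bright blobs and is deterministic", {
  set.seed(39)
  centers <- cbind(rep(c(20, 50, 80, 110, 140), 2),
                   rep(c(30, 90), each = 5))
  im <- blob_field(160, 120, centers, amp = 150, sigma = 2, bg = 5)
  res <- segment_channel(im, channel_params(median_radius_px = 6L))
  expect_equal(nrow(res$vesicles$table), 10)
  res2 <- segment_channel(im, channel_params(median_radius_px = 6L))
  expect_identical(res$vesicles$table, res2$vesicles$table)

  expect_warning(z <- segment_channel(calibrated_image(matrix(0, 32, 32), 100)))
  expect_equal(nrow(z$vesicles$table), 0)
  expect_false(any(z$mask))
})

test_that("detection recovers the true count on well-posed simulated fields", {
  # SNR >= 5, spacing >= 3 sigma, vesicles concentrated in the projection
  # window: the detected count should equal the truth in >= 95 % of fields
  hits <- 0
  n_fields <- 100
  for (i in seq_len(n_fields)) {
    p <- sim_params(seed = 5000 + i, field_shape = c(160L, 160L), n_cells = 1L,
                    cell_radius_um = 7, vesicles_per_cell_mean = 8,
                    red_only_per_cell_mean = 0, min_spacing_sigma = 3.5,
                    z_sd_slices = 0.3)
    sim <- simulate_field(p)
    start <- select_projection_window(sim$stack, "cargo", 3)
    proj <- max_intensity_projection(sim$stack, "cargo", start, 3)
    res <- segment_channel(proj, channel_params(median_radius_px = 6L))
    if (nrow(res$vesicles$table) == sum(sim$truth$vesicles$channel == "cargo")) {
      hits <- hits + 1
    }
  }
  expect_gte(hits / n_fields, 0.95)
})
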