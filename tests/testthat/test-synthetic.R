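small_params <- function(seed = 1, ...) {
  p <- sim_params(seed = seed, field_shape = c(160L, 160L), n_cells = 1L,
                  cell_radius_um = 7, vesicles_per_cell_mean = 10,
                  red_only_per_cell_mean = 3)
  update_sim_params(p, list(...))
}

test_that("a fixed seed reproduces the field and ground truth bit-for-bit", {
  s1 <- simulate_field(small_params(seed = 99))
  s2 <- simulate_field(small_params(seed = 99))
  expect_identical(s1$stack$slices, s2$stack$slices)
  expect_identical(s1$truth$vesicles, s2$truth$vesicles)
  s3 <- simulate_field(small_params(seed = 100))
  expect_false(identical(s1$stack$slices$cargo, s3$stack$slices$cargo))
})

test_that("zero vesicle mean leaves only background in the cargo channel", {
  sim <- simulate_field(small_params(seed = 2, vesicles_per_cell_mean = 0,
                                     red_only_per_cell_mean = 0))
  expect_equal(sum(sim$truth$vesicles$channel == "cargo"), 0)
  # no blob anywhere: intensities stay near background + noise
  expect_lt(max(sim$stack$slices$cargo),
            (small_params()$background_level * 1.2 +
               small_params()$extracellular_haze) * 2)
})

test_that("coloc fraction 1 pairs every cargo vesicle with a marker vesicle", {
  sim <- simulate_field(small_params(seed = 3, coloc_fraction = 1,
                                     vesicles_per_cell_mean = 25))
  green <- sim$truth$vesicles[sim$truth$vesicles$channel == "cargo", ]
  expect_gt(nrow(green), 0)
  expect_true(all(green$coloc))
})

test_that("ground truth counts are conserved and cells are labelled", {
  sim <- simulate_field(small_params(seed = 4))
  tr <- sim$truth
  expect_equal(tr$n_cells, 1)
  expect_true(all(tr$vesicles$cell_id %in% seq_len(tr$n_cells)))
  expect_equal(sort(unique(as.integer(tr$cell_labels))), c(0L, 1L))
  # vesicle centres lie inside the field
  expect_true(all(tr$vesicles$row >= 1 & tr$vesicles$row <= 160))
  expect_true(all(tr$vesicles$col >= 1 & tr$vesicles$col <= 160))
})

test_that("an impossibly dense field fails placement with advice", {
  expect_error(
    simulate_field(small_params(seed = 5, vesicles_per_cell_mean = 4000,
                                max_place_tries = 20L)),
    "density")
})

test_that("derived seeds are distinct over (field, time) pairs and below 2^31", {
  grid <- expand.grid(field = 1:20, time = c(0, 10, 25, 45, 60))
  seeds <- mapply(function(f, t) derive_seed(123, f, t), grid$field, grid$time)
  expect_equal(length(unique(seeds)), nrow(grid))
  expect_true(all(seeds > 0 & seeds < 2^31))
  expect_identical(derive_seed(123, 3, 25), derive_seed(123, 3, 25))
})

test_that("time-course simulation writes one stack and sidecar per field", {
  dir <- withr::local_tempdir()
  base <- small_params(seed = 8)
  man <- simulate_timecourse(base,
                             counts_by_time = c(`10` = 5, `25` = 8),
                             coloc_by_time = c(`10` = 0.6, `25` = 0.6),
                             n_fields = 3, dir = dir)
  expect_equal(nrow(man), 6)
  expect_true(all(file.exists(man$tiff)))
  expect_true(all(file.exists(man$sidecar)))
  sc <- jsonlite::read_json(man$sidecar[1], simplifyVector = TRUE)
  expect_equal(sc$time_min, 10)
  expect_equal(sc$n_cells, 1)
  # the written stack is readable and calibrated
  st <- read_stack(man$tiff[1], base$pixel_size_nm, base$z_step_um,
                   c("cargo", "marker", "nuclei"))
  expect_equal(n_slices(st), base$n_slices)
})

test_that("realized cargo counts follow the programmed Poisson mean", {
  # 50 fields at mean 42: the mean realized count per cell is within 3
  # (~3.3 standard errors of sqrt(42/50)) of 42
  counts <- numeric(50)
  for (i in 1:50) {
    p <- sim_params(seed = 7000 + i, field_shape = c(96L, 96L), n_cells = 1L,
                    cell_radius_um = 5, vesicles_per_cell_mean = 42,
                    red_only_per_cell_mean = 0, min_spacing_sigma = 1.5,
                    blob_amplitude = 0, background_level = 1,
                    extracellular_haze = 0)
    counts[i] <- sum(simulate_field(p)$truth$vesicles$channel == "cargo")
  }
  expect_lt(abs(mean(counts) - 42), 3)
})

test_that("realized colocalized fraction converges to the programmed fraction", {
  tot <- 0; pos <- 0
  for (i in 1:30) {
    p <- sim_params(seed = 7100 + i, field_shape = c(96L, 96L), n_cells = 1L,
                    cell_radius_um = 5, vesicles_per_cell_mean = 20,
                    coloc_fraction = 0.3, red_only_per_cell_mean = 0,
                    min_spacing_sigma = 1.5, blob_amplitude = 0,
                    background_level = 1, extracellular_haze = 0)
    g <- simulate_field(p)$truth$vesicles
    g <- g[g$channel == "cargo", ]
    tot <- tot + nrow(g); pos <- pos + sum(g$coloc)
  }
  # binomial tolerance: 4 * sqrt(0.3 * 0.7 / tot)
  expect_lt(abs(pos / tot - 0.3), 4 * sqrt(0.3 * 0.7 / tot))
})
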