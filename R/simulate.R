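#' Parameters for the synthetic confocal-field simulator
#'
#' Defines one simulated field of adherent cells imaged in three channels
#' (green = endocytosed cargo, red = endosome marker, blue = nuclear
#' stain). Vesicles are rendered as diffraction-limited 3-D Gaussian
#' blobs; a configurable fraction of green vesicles carries a coincident
#' red blob (true colocalization), and additional independent red-only
#' vesicles are present. Autofluorescent background with a lateral ramp,
#' diffuse extracellular cargo haze, Poisson shot noise and Gaussian read
#' noise complete the sensor model.
#'
#' @param seed integer master seed; fixes the entire field.
#' @param field_shape `(rows, cols)` in pixels.
#' @param pixel_size_nm lateral calibration (default 120 nm/px, a typical
#'   40x confocal zoom).
#' @param n_slices number of optical sections.
#' @param z_step_um axial step (default 0.5 um).
#' @param n_cells cells per field.
#' @param vesicles_per_cell_mean Poisson mean of green (cargo) vesicles
#'   per cell.
#' @param coloc_fraction probability that a green vesicle has a coincident
#'   red vesicle (in `[0, 1]`).
#' @param red_only_per_cell_mean Poisson mean of independent red-only
#'   vesicles per cell.
#' @param blob_sigma_nm lateral Gaussian sigma of a vesicle image
#'   (default 250 nm, about the diffraction-limited spot of a high-NA 40x
#'   objective).
#' @param blob_sigma_z_um axial Gaussian sigma (default 0.6 um).
#' @param blob_amplitude peak intensity of a vesicle above background.
#' @param background_level mean autofluorescence level (detector units).
#' @param background_gradient maximal fractional ramp of the background
#'   across the field (models uneven illumination).
#' @param noise_read_sigma standard deviation of Gaussian read noise;
#'   Poisson shot noise is always applied to signal plus background.
#' @param extracellular_haze amplitude of diffuse green background outside
#'   cells (models matrix-bound cargo labelling of intercellular space).
#' @param min_spacing_sigma minimum distance between distinct vesicles, in
#'   units of `blob_sigma_nm` (default 3, keeping detection well-posed).
#' @param cell_radius_um mean cell semi-major axis.
#' @param nucleus_axes_um semi-axes of the elliptical nucleus.
#' @param nucleus_amplitude peak intensity of the nuclear stain.
#' @param z_center_frac fraction of the stack depth where vesicles
#'   concentrate (basal/middle planes of the cell).
#' @param z_sd_slices axial spread of vesicle positions, in slices.
#' @param max_place_tries placement retries before giving up.
#' @return a `sim_params` list.
#' @export
sim_params <- function(seed = 1L,
                       field_shape = c(512L, 512L),
                       pixel_size_nm = 120,
                       n_slices = 5L,
                       z_step_um = 0.5,
                       n_cells = 4L,
                       vesicles_per_cell_mean = 28,
                       coloc_fraction = 0.5,
                       red_only_per_cell_mean = 8,
                       blob_sigma_nm = 250,
                       blob_sigma_z_um = 0.6,
                       blob_amplitude = 150,
                       background_level = 40,
                       background_gradient = 0.2,
                       noise_read_sigma = 3,
                       extracellular_haze = 10,
                       min_spacing_sigma = 3,
                       cell_radius_um = 12,
                       nucleus_axes_um = c(4, 3),
                       nucleus_amplitude = 180,
                       z_center_frac = 0.45,
                       z_sd_slices = 0.8,
                       max_place_tries = 200L) {
  p <- as.list(environment())
  stopifnot(p$coloc_fraction >= 0, p$coloc_fraction <= 1,
            p$blob_sigma_nm > 0, p$blob_amplitude >= 0,
            p$background_level >= 0, p$noise_read_sigma >= 0,
            p$pixel_size_nm > 0, p$n_slices >= 1)
  class(p) <- "sim_params"
  p
}

#' Merge overrides into simulator parameters
#' @param base a `sim_params` list.
#' @param overrides named list of fields to replace.
#' @return updated `sim_params`.
#' @export
update_sim_params <- function(base, overrides) {
  bad <- setdiff(names(overrides), names(base))
  if (length(bad) > 0) stop("unknown sim parameter(s): ", paste(bad, collapse = ", "), call. = FALSE)
  base[names(overrides)] <- overrides
  base
}

# uniform point inside an ellipse (centre cr/cc, semi-axes a/b, rotation th)
.sample_in_ellipse <- function(cr, cc, a, b, th) {
  u <- sqrt(stats::runif(1)); ang <- stats::runif(1, 0, 2 * pi)
  x <- a * u * cos(ang); y <- b * u * sin(ang)
  c(cr + x * cos(th) - y * sin(th), cc + x * sin(th) + y * cos(th))
}

# place n points inside an ellipse (clipped to the field) keeping min_dist
# from `existing` and from each other; bounded retries
.place_spaced <- function(n, cr, cc, a, b, th, min_dist, existing, max_tries,
                          field_dim) {
  pts <- matrix(numeric(0), ncol = 2)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (t in seq_len(max_tries)) {
      p <- .sample_in_ellipse(cr, cc, a, b, th)
      if (p[1] < 1 || p[1] > field_dim[1] || p[2] < 1 || p[2] > field_dim[2]) next
      all_pts <- rbind(existing, pts)
      if (nrow(all_pts) == 0 ||
          min(sqrt((all_pts[, 1] - p[1])^2 + (all_pts[, 2] - p[2])^2)) >= min_dist) {
        pts <- rbind(pts, p)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop("vesicle placement failed: density too high for the minimum spacing; ",
           "lower vesicles_per_cell_mean or min_spacing_sigma", call. = FALSE)
    }
  }
  pts
}

# add one 3-D Gaussian blob to a rows x cols x nz array (in place semantics
# via return); sigma_px lateral, sigma_z in slice units, z0 continuous slice
.render_blob <- function(arr, r0, c0, z0, amp, sigma_px, sigma_z) {
  d <- dim(arr)
  ext <- ceiling(4 * sigma_px)
  rlo <- max(1, round(r0) - ext); rhi <- min(d[1], round(r0) + ext)
  clo <- max(1, round(c0) - ext); chi <- min(d[2], round(c0) + ext)
  if (rlo > rhi || clo > chi) return(arr)
  rr <- rlo:rhi; cc <- clo:chi
  g <- exp(-((rr - r0)^2) / (2 * sigma_px^2)) %o%
       exp(-((cc - c0)^2) / (2 * sigma_px^2))
  for (z in seq_len(d[3])) {
    az <- exp(-((z - z0)^2) / (2 * sigma_z^2))
    if (az < 1e-4) next
    arr[rr, cc, z] <- arr[rr, cc, z] + amp * az * g
  }
  arr
}

#' Simulate one multi-channel confocal field with ground truth
#'
#' Cells are laid out on a jittered grid as rotated ellipses; each carries
#' an elliptical nucleus (blue channel) and a Poisson number of green
#' cargo vesicles placed inside the cell with a minimum mutual spacing.
#' Each green vesicle is, with probability `coloc_fraction`, accompanied
#' by a red vesicle at the same position; independent red-only vesicles
#' are added per cell. All vesicles are rendered as 3-D Gaussian blobs
#' across the optical sections, concentrated in the basal/middle planes.
#' Background ramp, extracellular haze (green), Poisson shot noise and
#' Gaussian read noise are then applied and intensities are rounded to
#' integer detector units.
#'
#' The same seed always reproduces the identical field and ground truth.
#'
#' @param params a [sim_params()] list.
#' @return list with `stack` (a [zstack_field()] with channels
#'   `cargo`, `marker`, `nuclei`) and `truth`: a list holding `vesicles`
#'   (data.frame: `channel`, `cell_id`, `row`, `col`, `z`, `coloc`),
#'   `nuclei` (centres), `cell_labels` (integer matrix), `n_cells`.
#' @export
simulate_field <- function(params = sim_params()) {
  set.seed(params$seed)
  nr <- params$field_shape[1]; nc <- params$field_shape[2]
  nz <- params$n_slices
  px_um <- params$pixel_size_nm / 1000
  sigma_px <- params$blob_sigma_nm / params$pixel_size_nm
  sigma_z <- params$blob_sigma_z_um / params$z_step_um
  min_dist <- params$min_spacing_sigma * sigma_px

  # --- cells on a jittered grid ---
  ncell <- params$n_cells
  gdim <- ceiling(sqrt(ncell))
  pitch_r <- nr / gdim; pitch_c <- nc / ceiling(ncell / gdim)
  cells <- data.frame(cell_id = seq_len(ncell), cr = NA_real_, cc = NA_real_,
                      a = NA_real_, b = NA_real_, theta = NA_real_)
  k <- 0L
  for (gi in seq_len(gdim)) {
    for (gj in seq_len(ceiling(ncell / gdim))) {
      if (k >= ncell) break
      k <- k + 1L
      cells$cr[k] <- (gi - 0.5) * pitch_r + stats::runif(1, -0.1, 0.1) * pitch_r
      cells$cc[k] <- (gj - 0.5) * pitch_c + stats::runif(1, -0.1, 0.1) * pitch_c
      cells$a[k] <- params$cell_radius_um / px_um * stats::runif(1, 0.85, 1.0)
      cells$b[k] <- cells$a[k] * stats::runif(1, 0.65, 0.9)
      cells$theta[k] <- stats::runif(1, 0, pi)
    }
  }

  # cell label image (first-placed cell wins where ellipses overlap)
  cell_labels <- matrix(0L, nr, nc)
  rowg <- matrix(seq_len(nr), nr, nc)
  colg <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  for (i in seq_len(ncell)) {
    dr <- rowg - cells$cr[i]; dc <- colg - cells$cc[i]
    xr <- dr * cos(cells$theta[i]) + dc * sin(cells$theta[i])
    yr <- -dr * sin(cells$theta[i]) + dc * cos(cells$theta[i])
    inside <- (xr / cells$a[i])^2 + (yr / cells$b[i])^2 <= 1
    cell_labels[inside & cell_labels == 0L] <- i
  }

  # --- vesicle placement ---
  ves <- data.frame(channel = character(0), cell_id = integer(0),
                    row = numeric(0), col = numeric(0), z = numeric(0),
                    coloc = logical(0))
  z_mu <- params$z_center_frac * (nz + 1)
  draw_z <- function(n) pmin(pmax(stats::rnorm(n, z_mu, params$z_sd_slices), 1), nz)
  all_xy <- matrix(numeric(0), ncol = 2)
  for (i in seq_len(ncell)) {
    n_green <- stats::rpois(1, params$vesicles_per_cell_mean)
    if (n_green > 0) {
      # keep vesicles off the nuclear footprint? not needed for detection;
      # biological realism of perinuclear exclusion is out of scope
      pts <- .place_spaced(n_green, cells$cr[i], cells$cc[i],
                           cells$a[i] * 0.95, cells$b[i] * 0.95, cells$theta[i],
                           min_dist, all_xy, params$max_place_tries, c(nr, nc))
      all_xy <- rbind(all_xy, pts)
      ves <- rbind(ves, data.frame(channel = "cargo", cell_id = i,
                                   row = pts[, 1], col = pts[, 2],
                                   z = draw_z(n_green),
                                   coloc = stats::runif(n_green) < params$coloc_fraction))
    }
    n_red <- stats::rpois(1, params$red_only_per_cell_mean)
    if (n_red > 0) {
      pts <- .place_spaced(n_red, cells$cr[i], cells$cc[i],
                           cells$a[i] * 0.95, cells$b[i] * 0.95, cells$theta[i],
                           min_dist, all_xy, params$max_place_tries, c(nr, nc))
      all_xy <- rbind(all_xy, pts)
      ves <- rbind(ves, data.frame(channel = "marker", cell_id = i,
                                   row = pts[, 1], col = pts[, 2],
                                   z = draw_z(n_red), coloc = NA))
    }
  }

  # --- rendering ---
  green <- array(0, dim = c(nr, nc, nz))
  red <- array(0, dim = c(nr, nc, nz))
  blue <- array(0, dim = c(nr, nc, nz))
  if (nrow(ves) > 0) {
    for (j in seq_len(nrow(ves))) {
      v <- ves[j, ]
      if (v$channel == "cargo") {
        green <- .render_blob(green, v$row, v$col, v$z, params$blob_amplitude,
                              sigma_px, sigma_z)
        if (isTRUE(v$coloc)) {
          red <- .render_blob(red, v$row, v$col, v$z, params$blob_amplitude,
                              sigma_px, sigma_z)
        }
      } else {
        red <- .render_blob(red, v$row, v$col, v$z, params$blob_amplitude,
                            sigma_px, sigma_z)
      }
    }
  }

  # nuclei: soft-edged ellipses, spread over the mid-stack
  nuc_a <- params$nucleus_axes_um[1] / px_um
  nuc_b <- params$nucleus_axes_um[2] / px_um
  nuc_prof <- exp(-((seq_len(nz) - (nz + 1) / 2)^2) / (2 * 1.5^2))
  for (i in seq_len(ncell)) {
    dr <- rowg - cells$cr[i]; dc <- colg - cells$cc[i]
    xr <- dr * cos(cells$theta[i]) + dc * sin(cells$theta[i])
    yr <- -dr * sin(cells$theta[i]) + dc * cos(cells$theta[i])
    e <- (xr / nuc_a)^2 + (yr / nuc_b)^2
    soft <- params$nucleus_amplitude / (1 + exp((e - 1) / 0.08))
    for (z in seq_len(nz)) blue[, , z] <- blue[, , z] + soft * nuc_prof[z]
  }

  # background ramp, haze, noise
  ramp <- 1 + params$background_gradient * (colg - 1) / max(nc - 1, 1)
  bg <- params$background_level * ramp
  haze <- params$extracellular_haze * (cell_labels == 0L)
  for (z in seq_len(nz)) {
    green[, , z] <- green[, , z] + bg + haze
    red[, , z] <- red[, , z] + bg
    blue[, , z] <- blue[, , z] + bg * 0.25
  }
  add_noise <- function(arr) {
    lam <- pmax(arr, 0)
    obs <- stats::rpois(length(lam), lam) + stats::rnorm(length(lam), 0, params$noise_read_sigma)
    arr[] <- pmax(round(obs), 0)
    arr
  }
  green <- add_noise(green); red <- add_noise(red); blue <- add_noise(blue)

  stack <- zstack_field(list(cargo = green, marker = red, nuclei = blue),
                        z_step_um = params$z_step_um,
                        pixel_size_nm = params$pixel_size_nm,
                        channels = c("cargo", "marker", "nuclei"))
  truth <- list(vesicles = ves,
                nuclei = cells[, c("cell_id", "cr", "cc")],
                cell_labels = cell_labels,
                n_cells = ncell,
                params = params)
  list(stack = stack, truth = truth)
}

#' Derive a per-field seed from a master seed
#'
#' Deterministic mixing of (master seed, field index, time point) into a
#' positive 32-bit seed, so a whole dataset is reproducible from one
#' integer and distinct (time, field) pairs get distinct streams.
#'
#' @param seed master seed.
#' @param field field index (1-based).
#' @param time_min time point in minutes.
#' @return integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, field, time_min) {
  s <- (as.double(seed) %% 2147483647) * 48271 + as.double(time_min) * 1000003 +
    as.double(field) * 7919
  as.integer(s %% 2147483646) + 1L
}

#' Simulate a time-course dataset of fields on disk
#'
#' Writes one multi-page TIFF (channel-interleaved per z-plane) and one
#' JSON ground-truth sidecar per field per time point. Per-field seeds are
#' derived deterministically from the base seed, field index and time.
#'
#' @param base a [sim_params()] list; its `vesicles_per_cell_mean` and
#'   `coloc_fraction` are overridden per time point.
#' @param counts_by_time named numeric vector: `time_min -> Poisson mean`
#'   of cargo vesicles per cell.
#' @param coloc_by_time named numeric vector: `time_min -> colocalized
#'   fraction`; names must match `counts_by_time`.
#' @param n_fields fields per time point.
#' @param dir output directory (created if needed).
#' @return data.frame manifest: `time_min`, `field`, `seed`, `tiff`,
#'   `sidecar`.
#' @export
simulate_timecourse <- function(base, counts_by_time, coloc_by_time, n_fields, dir) {
  if (length(counts_by_time) == 0) stop("need at least one time point", call. = FALSE)
  if (!setequal(names(counts_by_time), names(coloc_by_time))) {
    stop("counts_by_time and coloc_by_time must cover the same time points", call. = FALSE)
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (tm in names(counts_by_time)) {
    for (f in seq_len(n_fields)) {
      sd <- derive_seed(base$seed, f, as.numeric(tm))
      p <- update_sim_params(base, list(
        seed = sd,
        vesicles_per_cell_mean = unname(counts_by_time[[tm]]),
        coloc_fraction = unname(coloc_by_time[[tm]])))
      sim <- simulate_field(p)
      stem <- file.path(dir, sprintf("t%s_f%02d", tm, f))
      write_stack(sim$stack, paste0(stem, ".tif"), bits = 16L)
      sidecar <- list(time_min = as.numeric(tm), field = f, seed = sd,
                      n_cells = sim$truth$n_cells,
                      vesicles = sim$truth$vesicles,
                      nuclei = sim$truth$nuclei,
                      params = unclass(p)[setdiff(names(p), "field_shape")])
      sidecar$params$field_shape <- as.integer(p$field_shape)
      jsonlite::write_json(sidecar, paste0(stem, ".json"),
                           auto_unbox = TRUE, digits = NA, pretty = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        time_min = as.numeric(tm), field = f, seed = sd,
        tiff = paste0(stem, ".tif"), sidecar = paste0(stem, ".json"))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
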