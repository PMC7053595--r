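#' Binary mask with calibration
#'
#' @param pixels logical matrix.
#' @param pixel_size_nm calibration inherited from the source image.
#' @param threshold_used intensity threshold that produced the mask (optional).
#' @return an object of class `binary_mask`.
#' @export
binary_mask <- function(pixels, pixel_size_nm, threshold_used = NA_real_) {
  if (!is.matrix(pixels) || !is.logical(pixels)) {
    stop("`pixels` must be a logical matrix", call. = FALSE)
  }
  if (!is.numeric(pixel_size_nm) || pixel_size_nm <= 0) {
    stop("`pixel_size_nm` must be positive", call. = FALSE)
  }
  structure(pixels,
            pixel_size_nm = pixel_size_nm,
            threshold_used = threshold_used,
            class = c("binary_mask", "matrix", "array"))
}

#' Background suppression by subtraction of a median-filtered image
#'
#' Applies a disk-shaped median filter of the given radius (reflective
#' border handling) and subtracts the result from the original image,
#' clamping negative differences to zero. The median image estimates the
#' smooth background, so the difference sharpens the contrast between a
#' vesicle's edge pixels and the adjoining background and prevents
#' vesicles from being artificially enlarged when the image is later
#' binarized. Radii of 6 px for the cargo (green) channel and 10 px for
#' the marker (red) channel are the defaults used downstream.
#'
#' @param image a [calibrated_image()].
#' @param radius_px disk radius in pixels (>= 1); must not exceed half the
#'   shorter image side.
#' @return a [calibrated_image()] of background-subtracted intensities.
#' @export
median_subtract <- function(image, radius_px) {
  if (radius_px < 1) stop("`radius_px` must be >= 1", call. = FALSE)
  if (radius_px > min(dim(image)) / 2) {
    stop("median radius larger than half the image side", call. = FALSE)
  }
  x <- unclass(image)
  attributes(x) <- list(dim = dim(image))
  med <- disk_median_cpp(x, as.integer(radius_px))
  out <- pmax(x - med, 0)
  calibrated_image(out, pixel_size_nm = pixel_size_nm(image),
                   channel = attr(image, "channel"))
}

#' Otsu's threshold on a 256-bin intensity histogram
#'
#' Exhaustively maximizes the between-class variance over all bin
#' boundaries. For 8-bit data the bins coincide with the integer levels.
#'
#' @param x numeric vector or matrix of intensities.
#' @param n_bins histogram resolution (default 256).
#' @return threshold on the intensity scale; pixels strictly above it are
#'   foreground. `NA` if the image is constant.
#' @export
otsu_threshold <- function(x, n_bins = 256L) {
  v <- as.numeric(x)
  lo <- min(v); hi <- max(v)
  if (hi <= lo) return(NA_real_)
  # bin i covers [lo + (i-1)w, lo + iw); candidate thresholds are the upper
  # edges of bins 1..n_bins-1
  w <- (hi - lo) / n_bins
  bin <- pmin(floor((v - lo) / w), n_bins - 1)
  h <- tabulate(bin + 1L, nbins = n_bins)
  p <- h / sum(h)
  mids <- lo + (seq_len(n_bins) - 0.5) * w
  omega <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  k <- seq_len(n_bins - 1L)
  denom <- omega[k] * (1 - omega[k])
  sigma_b <- ifelse(denom > 0, (mu_t * omega[k] - mu[k])^2 / denom, -Inf)
  kstar <- which.max(sigma_b)
  lo + kstar * w
}

#' Binarize an image at a fixed or automatically chosen threshold
#'
#' Foreground is every pixel with intensity strictly greater than the
#' threshold. With `threshold = "auto"` the threshold maximizing Otsu's
#' between-class variance is used, a deterministic surrogate for picking
#' the value giving "maximal correspondence" between image and mask by
#' eye. Because Otsu's criterion always splits the histogram even when no
#' bright class exists, the automatic threshold is additionally floored
#' at a robust noise ceiling, the 75th percentile plus five interquartile
#' ranges of the image: on a signal-free field this leaves the mask
#' (essentially) empty instead of marking half the noise as foreground,
#' while on fields with genuine spots, which occupy a tiny pixel
#' fraction and do not move the quartiles, the floor sits well below the
#' Otsu value and has no effect. The threshold actually applied is
#' recorded on the mask.
#'
#' @param image a [calibrated_image()].
#' @param threshold a number, or `"auto"` for Otsu's method with the
#'   noise-floor guard.
#' @return a [binary_mask()]; its `threshold_used` attribute records the
#'   applied threshold. A constant image under `"auto"` yields an empty
#'   mask with a warning.
#' @export
binarize <- function(image, threshold = "auto") {
  if (identical(threshold, "auto")) {
    threshold <- otsu_threshold(image)
    if (is.na(threshold)) {
      warning("constant image: automatic threshold undefined, returning empty mask")
      return(binary_mask(matrix(FALSE, nrow(image), ncol(image)),
                         pixel_size_nm(image), threshold_used = NA_real_))
    }
    q <- stats::quantile(as.numeric(image), c(0.25, 0.75), names = FALSE)
    threshold <- max(threshold, q[2] + 5 * (q[2] - q[1]))
  }
  m <- unclass(image) > threshold
  dim(m) <- dim(image)
  binary_mask(m, pixel_size_nm(image), threshold_used = threshold)
}

#' Particle analysis: connected components with a calibrated area filter
#'
#' Labels connected foreground components (8-connectivity by default) and
#' keeps those whose physical area, pixel count times `pixel_size_nm`
#' squared, is strictly greater than `min_area_nm2`; a component of
#' exactly the threshold area is rejected. Surviving components are
#' relabelled 1..n in raster-scan order of their first pixel.
#'
#' @param mask a [binary_mask()].
#' @param min_area_nm2 minimum object area in square nanometres
#'   (default 20000, the conventional lower bound for a resolvable vesicle).
#' @param connectivity 4 or 8 (default 8).
#' @return a `vesicle_set`: list with `table` (one row per retained object:
#'   `label`, `n_px`, `area_nm2`), `labels` (relabelled image),
#'   `pixel_size_nm`, `channel`, `n_cells` (NA until set).
#' @export
label_particles <- function(mask, min_area_nm2 = 20000, connectivity = 8L) {
  ps <- attr(mask, "pixel_size_nm")
  if (is.null(ps)) stop("mask carries no pixel-size calibration", call. = FALSE)
  if (!connectivity %in% c(4L, 8L)) stop("`connectivity` must be 4 or 8", call. = FALSE)
  m <- unclass(mask)
  attributes(m) <- list(dim = dim(mask))
  lab <- label_components_cpp(m, as.integer(connectivity))
  n0 <- max(lab)
  px_area <- ps^2
  if (n0 == 0) {
    tab <- data.frame(label = integer(0), n_px = integer(0), area_nm2 = numeric(0))
  } else {
    counts <- tabulate(lab[lab > 0], nbins = n0)
    keep <- which(counts * px_area > min_area_nm2)
    relab <- integer(n0)
    relab[keep] <- seq_along(keep)  # original ids are raster-ordered already
    lab[] <- ifelse(lab > 0, relab[pmax(lab, 1L)], 0L)
    tab <- data.frame(label = seq_along(keep),
                      n_px = counts[keep],
                      area_nm2 = counts[keep] * px_area)
  }
  structure(list(table = tab, labels = lab, pixel_size_nm = ps,
                 channel = NA_character_, n_cells = NA_integer_),
            class = "vesicle_set")
}

#' @export
print.vesicle_set <- function(x, ...) {
  cat(sprintf("<vesicle_set> %d objects (channel %s, %.1f nm/px, n_cells = %s)\n",
              nrow(x$table), x$channel, x$pixel_size_nm,
              ifelse(is.na(x$n_cells), "?", x$n_cells)))
  invisible(x)
}

#' Measure detected vesicles on the source projection
#'
#' Fills in, for every object, its centroid (pixel coordinates) and its
#' integrated density, the sum of source-image intensities over the
#' object's pixels, plus the per-object mean intensity. Measurement is
#' taken on the original (pre-subtraction) projection: the mask only
#' selects pixels, it does not alter intensities.
#'
#' @param image the pre-subtraction [calibrated_image()] the mask was
#'   derived from (same shape).
#' @param vesicles a `vesicle_set` from [label_particles()].
#' @return the `vesicle_set` with `centroid_row`, `centroid_col`,
#'   `integral_density` and `mean_intensity` columns filled in.
#' @export
measure_vesicles <- function(image, vesicles) {
  if (!all(dim(image) == dim(vesicles$labels))) {
    stop("image and label shapes differ", call. = FALSE)
  }
  tab <- vesicles$table
  if (nrow(tab) == 0) {
    tab$centroid_row <- numeric(0); tab$centroid_col <- numeric(0)
    tab$integral_density <- numeric(0); tab$mean_intensity <- numeric(0)
    vesicles$table <- tab
    return(vesicles)
  }
  lab <- vesicles$labels
  idx <- which(lab > 0)
  l <- lab[idx]
  rows <- (idx - 1L) %% nrow(lab) + 1L
  cols <- (idx - 1L) %/% nrow(lab) + 1L
  vals <- unclass(image)[idx]
  n <- nrow(tab)
  tab$centroid_row <- as.numeric(tapply(rows, factor(l, levels = seq_len(n)), mean))
  tab$centroid_col <- as.numeric(tapply(cols, factor(l, levels = seq_len(n)), mean))
  tab$integral_density <- as.numeric(tapply(vals, factor(l, levels = seq_len(n)), sum))
  tab$mean_intensity <- tab$integral_density / tab$n_px
  vesicles$table <- tab
  vesicles
}

#' Count cells in a field
#'
#' Either counts the distinct nonzero labels of an externally supplied
#' cell-mask image, or detects nuclei in a nuclei-channel image by
#' automatic thresholding and connected-component labelling with a
#' nucleus-scale minimum area.
#'
#' @param nuclei_image a [calibrated_image()] of the nuclear stain
#'   (e.g. Hoechst), or `NULL`.
#' @param cell_masks integer label matrix of cell identities, or `NULL`.
#' @param min_area_um2 minimum nucleus area in square micrometres when
#'   detecting from the nuclei image (default 20).
#' @return integer cell count.
#' @export
count_cells <- function(nuclei_image = NULL, cell_masks = NULL, min_area_um2 = 20) {
  if (is.null(nuclei_image) && is.null(cell_masks)) {
    stop("supply either `nuclei_image` or `cell_masks`", call. = FALSE)
  }
  if (!is.null(cell_masks)) {
    return(length(setdiff(unique(as.integer(cell_masks)), 0L)))
  }
  thr <- otsu_threshold(nuclei_image)
  if (is.na(thr)) {
    warning("blank nuclei image: 0 cells")
    return(0L)
  }
  mask <- binarize(nuclei_image, threshold = thr)
  nuclei <- label_particles(mask, min_area_nm2 = min_area_um2 * 1e6, connectivity = 8L)
  n <- nrow(nuclei$table)
  if (n == 0) warning("no nuclei above the minimum area: 0 cells")
  n
}

#' Default per-channel segmentation parameters
#'
#' @param median_radius_px disk radius for [median_subtract()]; 6 is the
#'   cargo-channel default, 10 the marker-channel default.
#' @param threshold `"auto"` (Otsu) or a fixed number.
#' @param min_area_nm2 strict lower area bound for [label_particles()].
#' @param connectivity 4 or 8.
#' @param extra_preprocess run a second median-subtraction pass (radius
#'   `extra_radius_px`) before binarization; an approximation of the
#'   heavier pre-processing some late-endosome/lysosome (LAMP1-type)
#'   images need.
#' @param extra_radius_px radius of the optional second pass.
#' @return a named list of parameters for [segment_channel()].
#' @export
channel_params <- function(median_radius_px = 6L, threshold = "auto",
                           min_area_nm2 = 20000, connectivity = 8L,
                           extra_preprocess = FALSE, extra_radius_px = 20L) {
  list(median_radius_px = median_radius_px, threshold = threshold,
       min_area_nm2 = min_area_nm2, connectivity = connectivity,
       extra_preprocess = extra_preprocess, extra_radius_px = extra_radius_px)
}

#' Segment one projected channel into vesicles
#'
#' Composes the full detection chain: optional extra median-subtraction
#' pass, median-filter background subtraction, binarization, particle
#' labelling with the calibrated area filter, and measurement of the
#' retained objects on the original projection.
#'
#' @param projection the channel's [calibrated_image()] projection.
#' @param params a list from [channel_params()].
#' @return list with `vesicles` (measured `vesicle_set`), `mask` (the
#'   [binary_mask()], needed for object-based colocalization) and
#'   `threshold_used`.
#' @export
segment_channel <- function(projection, params = channel_params()) {
  work <- projection
  if (isTRUE(params$extra_preprocess)) {
    work <- median_subtract(work, params$extra_radius_px)
  }
  work <- median_subtract(work, params$median_radius_px)
  mask <- binarize(work, threshold = params$threshold)
  ves <- label_particles(mask, min_area_nm2 = params$min_area_nm2,
                         connectivity = params$connectivity)
  ves$channel <- attr(projection, "channel")
  ves <- measure_vesicles(projection, ves)
  list(vesicles = ves, mask = mask, threshold_used = attr(mask, "threshold_used"))
}

#' Per-field summary of a measured vesicle set
#'
#' @param vesicles a measured `vesicle_set`.
#' @param n_cells number of cells in the field (for the per-cell count).
#' @return one-row data.frame: `n_vesicles`, `n_cells`,
#'   `vesicles_per_cell`, `mean_integral_density`, `mean_mean_intensity`.
#' @export
summarize_vesicles <- function(vesicles, n_cells = vesicles$n_cells) {
  tab <- vesicles$table
  data.frame(
    n_vesicles = nrow(tab),
    n_cells = as.integer(n_cells),
    vesicles_per_cell = if (!is.na(n_cells) && n_cells > 0) nrow(tab) / n_cells else NA_real_,
    mean_integral_density = if (nrow(tab) > 0) mean(tab$integral_density) else NA_real_,
    mean_mean_intensity = if (nrow(tab) > 0) mean(tab$mean_intensity) else NA_real_
  )
}
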