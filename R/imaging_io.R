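#' Calibrated single-channel image
#'
#' A 2-D intensity image together with the physical size of one pixel and
#' the role of the channel it came from. Intensities are in arbitrary
#' detector units and must be non-negative; no rescaling is applied on
#' construction.
#'
#' @param pixels numeric matrix of non-negative intensities.
#' @param pixel_size_nm physical edge length of one pixel, in nanometres
#'   (must be positive).
#' @param channel role label: one of `"cargo"`, `"marker"`, `"nuclei"`.
#' @return an object of class `calibrated_image`: the pixel matrix with
#'   `pixel_size_nm` and `channel` attributes.
#' @export
calibrated_image <- function(pixels, pixel_size_nm, channel = "cargo") {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  }
  if (!is.numeric(pixel_size_nm) || length(pixel_size_nm) != 1 ||
      !is.finite(pixel_size_nm) || pixel_size_nm <= 0) {
    stop("`pixel_size_nm` must be a single positive number", call. = FALSE)
  }
  if (any(pixels < 0, na.rm = TRUE)) {
    stop("intensities must be non-negative", call. = FALSE)
  }
  channel <- match.arg(channel, c("cargo", "marker", "nuclei"))
  structure(pixels,
            pixel_size_nm = pixel_size_nm,
            channel = channel,
            class = c("calibrated_image", "matrix", "array"))
}

#' @export
print.calibrated_image <- function(x, ...) {
  cat(sprintf("<calibrated_image> %d x %d px, %.1f nm/px, channel = %s\n",
              nrow(x), ncol(x), attr(x, "pixel_size_nm"), attr(x, "channel")))
  invisible(x)
}

#' Pixel calibration of an image or mask
#' @param x a `calibrated_image`, `binary_mask` or `zstack_field`.
#' @return pixel size in nm.
#' @export
pixel_size_nm <- function(x) {
  ps <- if (is.list(x)) x$pixel_size_nm else attr(x, "pixel_size_nm")
  if (is.null(ps)) stop("object carries no pixel-size calibration", call. = FALSE)
  ps
}

#' Multi-channel confocal z-stack field
#'
#' Holds one field of view: for every channel an ordered set of optical
#' sections (bottom of the cell first), plus the axial step and lateral
#' pixel calibration.
#'
#' @param slices named list, one element per channel, each a 3-D array
#'   `rows x cols x n_slices` (or a list of equally sized matrices).
#' @param z_step_um spacing between optical sections in micrometres.
#' @param pixel_size_nm lateral pixel size in nanometres.
#' @param channels ordered character vector of role labels; defaults to
#'   `names(slices)`.
#' @return an object of class `zstack_field`.
#' @export
zstack_field <- function(slices, z_step_um, pixel_size_nm, channels = names(slices)) {
  if (!is.list(slices) || length(slices) == 0) {
    stop("`slices` must be a non-empty list of per-channel arrays", call. = FALSE)
  }
  if (is.null(channels) || length(channels) != length(slices)) {
    stop("`channels` must label every element of `slices`", call. = FALSE)
  }
  slices <- lapply(slices, function(s) {
    if (is.list(s)) s <- simplify2array(s)
    if (is.matrix(s)) s <- array(s, dim = c(dim(s), 1L))
    if (length(dim(s)) != 3) stop("each channel needs a rows x cols x slices array", call. = FALSE)
    s
  })
  dims <- lapply(slices, dim)
  if (length(unique(lapply(dims, identity))) != 1) {
    stop("all channels must share one shape and slice count", call. = FALSE)
  }
  if (!is.numeric(z_step_um) || z_step_um <= 0) {
    stop("`z_step_um` must be positive", call. = FALSE)
  }
  if (!is.numeric(pixel_size_nm) || pixel_size_nm <= 0) {
    stop("`pixel_size_nm` must be positive", call. = FALSE)
  }
  names(slices) <- channels
  structure(list(slices = slices,
                 z_step_um = z_step_um,
                 pixel_size_nm = pixel_size_nm,
                 channels = channels),
            class = "zstack_field")
}

#' @export
print.zstack_field <- function(x, ...) {
  d <- dim(x$slices[[1]])
  cat(sprintf("<zstack_field> %d x %d px, %d slices (dz = %g um), %.1f nm/px, channels: %s\n",
              d[1], d[2], d[3], x$z_step_um, x$pixel_size_nm,
              paste(x$channels, collapse = ", ")))
  invisible(x)
}

#' Number of optical sections in a field
#' @param stack a `zstack_field`.
#' @return slice count.
#' @export
n_slices <- function(stack) dim(stack$slices[[1]])[3]

#' Read a multi-page TIFF into a calibrated z-stack field
#'
#' Pages are expected channel-interleaved per z-plane: with channels
#' `(c1, c2)` the page order is `z1c1, z1c2, z2c1, z2c2, ...`. Intensities
#' are read bit-exactly (8- or 16-bit grayscale); no rescaling.
#'
#' @param path path to the TIFF file.
#' @param pixel_size_nm lateral calibration in nm/pixel (required; TIFF
#'   metadata is not trusted for physical scale).
#' @param z_step_um axial step between optical sections, in micrometres.
#' @param channel_order character vector of role labels in page order
#'   within each z-plane.
#' @return a [zstack_field()].
#' @export
read_stack <- function(path, pixel_size_nm, z_step_um, channel_order) {
  if (!file.exists(path)) stop("cannot read stack: file not found: ", path, call. = FALSE)
  if (pixel_size_nm <= 0 || z_step_um <= 0) {
    stop("calibration values must be positive", call. = FALSE)
  }
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (is.matrix(pages)) pages <- list(pages)
  nch <- length(channel_order)
  if (length(pages) %% nch != 0) {
    stop(sprintf("page count (%d) is not divisible by channel count (%d)",
                 length(pages), nch), call. = FALSE)
  }
  nz <- length(pages) %/% nch
  slices <- lapply(seq_len(nch), function(ci) {
    idx <- (seq_len(nz) - 1L) * nch + ci
    simplify2array(lapply(pages[idx], function(p) {
      storage.mode(p) <- "double"
      p
    }))
  })
  names(slices) <- channel_order
  zstack_field(slices, z_step_um = z_step_um, pixel_size_nm = pixel_size_nm,
               channels = channel_order)
}

#' Write a z-stack field as a channel-interleaved multi-page TIFF
#'
#' Intensities are rounded to integers and stored at the requested bit
#' depth; values outside the representable range are clipped. A stack
#' written and re-read with matching parameters reproduces integer data
#' exactly.
#'
#' @param stack a `zstack_field`.
#' @param path output path.
#' @param bits bits per sample, 8 or 16.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, bits = 16L) {
  if (!bits %in% c(8L, 16L)) stop("`bits` must be 8 or 16", call. = FALSE)
  maxval <- 2^bits - 1
  nz <- n_slices(stack)
  pages <- vector("list", nz * length(stack$channels))
  k <- 1L
  for (z in seq_len(nz)) {
    for (ch in stack$channels) {
      p <- pmin(pmax(round(stack$slices[[ch]][, , z]), 0), maxval)
      pages[[k]] <- p / maxval
      k <- k + 1L
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = bits, compression = "none")
  invisible(path)
}

#' Maximum-intensity projection over consecutive optical sections
#'
#' Every output pixel is the maximum of that pixel over `n_slices`
#' consecutive sections starting at `start_slice`. The default window of
#' three sections matches common practice for quantifying vesicles that
#' sit in the basal and middle planes of adherent cells.
#'
#' @param stack a `zstack_field`.
#' @param channel role label of the channel to project.
#' @param start_slice 1-based index of the first section in the window.
#' @param n_slices number of consecutive sections (default 3); use
#'   `n_slices = "all"` for a full-stack projection.
#' @return a [calibrated_image()] with calibration propagated unchanged.
#' @export
max_intensity_projection <- function(stack, channel, start_slice = 1L, n_slices = 3L) {
  arr <- stack$slices[[channel]]
  if (is.null(arr)) stop("no such channel: ", channel, call. = FALSE)
  nz <- dim(arr)[3]
  if (identical(n_slices, "all")) { start_slice <- 1L; n_slices <- nz }
  if (start_slice < 1 || start_slice + n_slices - 1 > nz) {
    stop(sprintf("projection window [%d, %d] exceeds stack depth %d",
                 start_slice, start_slice + n_slices - 1, nz), call. = FALSE)
  }
  win <- arr[, , start_slice:(start_slice + n_slices - 1), drop = FALSE]
  proj <- apply(win, c(1, 2), max)
  calibrated_image(proj, pixel_size_nm = stack$pixel_size_nm, channel = channel)
}

#' Choose the projection window with maximal summed intensity
#'
#' Deterministic surrogate for the visual choice of the "base and middle"
#' sections: returns the 1-based start index of the `n_slices`-long window
#' whose summed intensity in the given channel is maximal. Ties break to
#' the lowest start index.
#'
#' @inheritParams max_intensity_projection
#' @return integer start index.
#' @export
select_projection_window <- function(stack, channel, n_slices = 3L) {
  arr <- stack$slices[[channel]]
  if (is.null(arr)) stop("no such channel: ", channel, call. = FALSE)
  nz <- dim(arr)[3]
  if (nz < n_slices) {
    stop(sprintf("stack depth %d is shallower than the %d-slice window", nz, n_slices),
         call. = FALSE)
  }
  totals <- apply(arr, 3, sum)
  wins <- vapply(seq_len(nz - n_slices + 1L),
                 function(s) sum(totals[s:(s + n_slices - 1L)]), numeric(1))
  which.max(wins)  # which.max takes the first maximum: lowest-index tie-break
}
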