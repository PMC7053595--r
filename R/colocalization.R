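#' Object-based colocalization by ROI superposition
#'
#' Superimposes the detected objects of channel A (typically the cargo)
#' onto the binarized image of channel B (typically an endosome marker).
#' An object counts as overlapping when at least `min_overlap_px` of its
#' pixels fall on channel-B foreground; the result is the percentage of
#' overlapping objects out of all channel-A objects.
#'
#' The measure is directional: A-objects against the B mask is not the
#' same quantity as B-objects against the A mask. Call the function with
#' the arguments swapped to obtain the reverse direction.
#'
#' @param vesicles_a measured `vesicle_set` of channel A.
#' @param mask_b [binary_mask()] of channel B (same shape and calibration).
#' @param min_overlap_px minimum number of shared pixels for an object to
#'   count as overlapping (default 1, the weakest reading of "overlap").
#' @param field_id optional identifier carried into the result.
#' @return one-row data.frame of class `coloc_result`: `field_id`,
#'   `channel_a`, `channel_b`, `n_objects_a`, `n_overlapping`,
#'   `percent_coloc` (`NA`, not 0, when there are no A-objects) and
#'   `min_overlap_px`.
#' @export
object_overlap <- function(vesicles_a, mask_b, min_overlap_px = 1L, field_id = NA_character_) {
  if (!all(dim(vesicles_a$labels) == dim(mask_b))) {
    stop("vesicle labels and mask shapes differ", call. = FALSE)
  }
  if (!isTRUE(all.equal(vesicles_a$pixel_size_nm, attr(mask_b, "pixel_size_nm")))) {
    stop("vesicle set and mask calibrations differ", call. = FALSE)
  }
  n_a <- nrow(vesicles_a$table)
  if (n_a == 0) {
    n_over <- 0L
    pct <- NA_real_
  } else {
    lab <- vesicles_a$labels
    fg <- lab > 0 & unclass(mask_b)
    over_px <- tabulate(lab[fg], nbins = n_a)
    n_over <- sum(over_px >= min_overlap_px)
    pct <- 100 * n_over / n_a
  }
  res <- data.frame(field_id = field_id,
                    channel_a = vesicles_a$channel,
                    channel_b = "marker",
                    n_objects_a = n_a,
                    n_overlapping = n_over,
                    percent_coloc = pct,
                    min_overlap_px = as.integer(min_overlap_px))
  class(res) <- c("coloc_result", "data.frame")
  res
}

#' Summarize colocalization percentages along a time course
#'
#' Groups per-field colocalization percentages by time point and reports
#' the boxplot statistics (median, quartiles, minimum, maximum) plus the
#' number of fields, i.e. the distributional summary used for reporting
#' internalization time courses. Fields with an undefined percentage
#' (no objects) are dropped from the distribution, not treated as 0.
#'
#' @param fields data.frame with columns `time_min` and `percent_coloc`
#'   (e.g. row-bound [object_overlap()] results with a `time_min` column).
#' @return data.frame with one row per time point: `time_min`, `n`,
#'   `median`, `q1`, `q3`, `min`, `max`.
#' @export
coloc_timecourse <- function(fields) {
  if (is.null(fields) || nrow(fields) == 0) {
    stop("need at least one field", call. = FALSE)
  }
  if (!all(c("time_min", "percent_coloc") %in% names(fields))) {
    stop("`fields` needs columns time_min and percent_coloc", call. = FALSE)
  }
  fields <- fields[!is.na(fields$percent_coloc), , drop = FALSE]
  if (nrow(fields) == 0) stop("no fields with a defined colocalization percentage", call. = FALSE)
  out <- do.call(rbind, lapply(split(fields, fields$time_min), function(g) {
    bs <- box_summary(g$percent_coloc)
    data.frame(time_min = g$time_min[1], n = bs$n, median = bs$median,
               q1 = bs$q1, q3 = bs$q3, min = bs$min, max = bs$max)
  }))
  out <- out[order(out$time_min), , drop = FALSE]
  rownames(out) <- NULL
  out
}
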