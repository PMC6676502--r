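#' Build the measurement and background masks
#'
#' Partitions the in-selection pixels into the measurement mask (the union
#' of all particle pixel sets, intersected with the selection) and the
#' background mask (every other in-selection pixel). The two masks are
#' disjoint and together cover the selection exactly; background intensity
#' is estimated from the latter.
#'
#' @param particles An `fq_particles` table from [analyze_particles()].
#' @param selection A [selection_region()].
#' @param dim Image dimensions `c(height, width)`; defaults to the
#'   dimensions recorded on `particles`.
#' @return A list of class `mask_pair` with logical matrices
#'   `measurement_mask` and `background_mask`.
#' @export
build_masks <- function(particles, selection = whole_image(), dim = NULL) {
  dim <- dim %||% attr(particles, "dim_image")
  if (is.null(dim)) stop("input error: image dimensions unknown")
  sel <- selection_mask(selection, dim)
  meas <- matrix(FALSE, dim[1], dim[2])
  px <- unlist(particles$pixels)
  if (length(px)) {
    if (max(px) > prod(dim)) {
      stop("input error: particle pixels fall outside the image")
    }
    meas[px] <- TRUE
  }
  meas <- meas & sel
  structure(list(measurement_mask = meas, background_mask = sel & !meas),
            class = "mask_pair")
}

#' Measure mean query intensity inside each particle
#'
#' Superimposes marker-derived particles onto the query channel and takes
#' the arithmetic mean of the query intensities over each particle's pixel
#' set (double precision).
#'
#' @param query A [channel_image()] with the same dimensions as the
#'   segmentation channel.
#' @param particles An `fq_particles` table.
#' @return Tibble with `roi_id`, `mean_raw`, `area_px`, `centroid_x`,
#'   `centroid_y`.
#' @export
measure_rois <- function(query, particles) {
  dims <- attr(particles, "dim_image")
  if (!is.null(dims) && !all(dim(query) == dims)) {
    stop("input error: query dimensions ", paste(dim(query), collapse = "x"),
         " do not match segmentation channel ", paste(dims, collapse = "x"))
  }
  q <- as_intensity(query)
  tibble::tibble(
    roi_id = particles$label,
    mean_raw = vapply(particles$pixels, function(px) mean(q[px]), double(1)),
    area_px = particles$area,
    centroid_x = particles$centroid_x,
    centroid_y = particles$centroid_y
  )
}

#' Measure the image background on the query channel
#'
#' The background estimate is the mean (or median, if configured) query
#' intensity over the background mask — all in-selection pixels not claimed
#' by any particle. One global value per image.
#'
#' @inheritParams measure_rois
#' @param masks A `mask_pair` from [build_masks()].
#' @param stat `"mean"` (default, matching ImageJ's Measure) or `"median"`.
#' @return A single background intensity.
#' @export
measure_background <- function(query, masks, stat = c("mean", "median")) {
  stat <- match.arg(stat)
  stopifnot(inherits(masks, "mask_pair"))
  bg <- masks$background_mask
  if (!any(bg)) {
    stop("input error: background mask is empty; background is undefined. ",
         "Use a larger selection or stricter particle filters.")
  }
  vals <- as_intensity(query)[bg]
  if (stat == "mean") mean(vals) else median(vals)
}

#' Quantify one image end to end
#'
#' Runs the full pipeline on a marker/query channel pair: clear outside the
#' selection, threshold the marker (automatically unless a manual
#' [threshold_spec()] is given), optionally dilate and watershed-split the
#' mask (in that order), run the particle analysis, apply include/exclude
#' edits, build the measurement/background mask pair, and measure.
#' Each particle's corrected intensity is its mean query intensity minus
#' the shared image background; negative corrected means are kept (clipping
#' would bias downstream fold-changes) and flagged with a warning.
#'
#' @param marker Marker [channel_image()] (defines the ROIs).
#' @param query Query `channel_image` (intensities measured).
#' @param selection A [selection_region()].
#' @param threshold A [threshold_spec()], or `NULL` to auto-threshold.
#' @param filter A [particle_filter()].
#' @param include_ids,exclude_ids Optional label edits, see
#'   [edit_particles()].
#' @param image_id Identifier written into the result rows.
#' @param bg_stat Background statistic, `"mean"` or `"median"`.
#' @param threshold_method Auto-threshold algorithm when `threshold` is
#'   `NULL`.
#' @param integrated_density Also report `int_den = mean_raw * area_px`.
#' @return A tibble of class `fq_quant`, one row per surviving ROI with
#'   columns `image`, `roi_id`, `area_px`, `mean_raw`, `mean_bg`,
#'   `mean_corrected`, `centroid_x`, `centroid_y`. Attributes carry the
#'   resolved threshold (`threshold`), the particle table (`particles`),
#'   the image id and the background value. [glance()] returns the one-row
#'   image summary (unweighted mean of `mean_corrected` across ROIs).
#' @examples
#' syn <- generate_image(synth_spec(n_nuclei = 4, seed = 1))
#' ch <- split_channels(syn$stack)
#' res <- quantify_image(ch$red, ch$green, image_id = "demo")
#' glance(res)
#' @export
quantify_image <- function(marker, query, selection = whole_image(),
                           threshold = NULL, filter = particle_filter(),
                           include_ids = NULL, exclude_ids = NULL,
                           image_id = "image",
                           bg_stat = c("mean", "median"),
                           threshold_method = c("isodata", "otsu"),
                           integrated_density = FALSE) {
  bg_stat <- match.arg(bg_stat)
  threshold_method <- match.arg(threshold_method)
  if (!all(dim(marker) == dim(query))) {
    stop("input error: marker and query dimensions differ")
  }
  cleared <- in_stage("clear_outside_selection",
                      clear_outside_selection(marker, selection))
  spec <- if (is.null(threshold)) {
    in_stage("auto_threshold",
             auto_threshold(cleared, selection, method = threshold_method))
  } else threshold
  mask <- in_stage("apply_threshold",
                   apply_threshold(cleared, spec, selection))
  if (filter$apply_dilate) {
    mask <- in_stage("binary_dilate",
                     binary_dilate(mask, filter$dilate_iterations))
  }
  if (filter$apply_watershed) {
    mask <- in_stage("binary_watershed", binary_watershed(mask))
  }
  parts <- in_stage("analyze_particles", analyze_particles(mask, filter))
  parts <- in_stage("edit_particles",
                    edit_particles(parts, include_ids, exclude_ids))
  masks <- in_stage("build_masks", build_masks(parts, selection, dim(marker)))
  rois <- in_stage("measure_rois", measure_rois(query, parts))
  mean_bg <- if (nrow(rois) > 0 || any(masks$background_mask)) {
    in_stage("measure_background",
             measure_background(query, masks, stat = bg_stat))
  } else NA_real_
  out <- tibble::tibble(
    image = rep(image_id, nrow(rois)),
    roi_id = rois$roi_id,
    area_px = rois$area_px,
    mean_raw = rois$mean_raw,
    mean_bg = rep(mean_bg, nrow(rois)),
    mean_corrected = rois$mean_raw - mean_bg,
    centroid_x = rois$centroid_x,
    centroid_y = rois$centroid_y
  )
  if (integrated_density) out$int_den <- out$mean_raw * out$area_px
  neg <- out$roi_id[!is.na(out$mean_corrected) & out$mean_corrected < 0]
  if (length(neg)) {
    warning("negative corrected mean for ROI(s) ",
            paste(neg, collapse = ", "), " in ", image_id,
            " (reported, not clipped)")
  }
  structure(out,
            class = c("fq_quant", class(out)),
            image_id = image_id, mean_bg = mean_bg, threshold = spec,
            particles = parts, negative_rois = neg)
}

#' @export
glance.fq_quant <- function(x, ...) {
  tibble::tibble(
    image = attr(x, "image_id"),
    n_rois = nrow(x),
    mean_corrected_mean = if (nrow(x)) mean(x$mean_corrected) else NA_real_,
    mean_bg = attr(x, "mean_bg")
  )
}

#' @export
tidy.fq_quant <- function(x, ...) {
  tibble::as_tibble(x)
}
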