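#' Read a multi-slice RGB TIFF into an 8-bit stack
#'
#' Loads a baseline TIFF whose pixels carry three colour samples (red, green,
#' blue) and returns every slice as an integer array on the 8-bit scale.
#' 16-bit inputs are accepted and linearly rescaled to `[0, 255]` (division by
#' 257 and rounding); the rescale is reported with a message so it appears in
#' run logs. Grayscale or RGBA TIFFs are rejected: the pipeline's contract is
#' one marker and one query channel inside an RGB image.
#'
#' @param path Path to a `.tif` file.
#' @return An object of class `rgb_stack`: a list with `planes` (a list of
#'   `height x width x 3` integer arrays, values in 0--255), `height`,
#'   `width`, `n_slices`, `bits_per_sample` and `source_path`.
#' @seealso [split_channels()], [write_rgb_stack()]
#' @export
read_rgb_stack <- function(path) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    stop("input error: file not found: ", path)
  }
  info <- tiff::readTIFF(path, payload = FALSE, all = TRUE)
  spp <- unique(info$samples.per.pixel)
  if (length(spp) != 1L || spp != 3L) {
    stop("format error: expected 3 colour samples per pixel, found ",
         paste(spp, collapse = "/"),
         " (grayscale or alpha TIFFs are not supported)")
  }
  bits <- max(info$bits.per.sample)
  slices <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(slices)) slices <- list(slices)
  dims <- unique(lapply(slices, function(s) dim(s)[1:2]))
  if (length(dims) != 1L) {
    stop("format error: slices disagree on dimensions")
  }
  if (bits > 8L) {
    message("read_rgb_stack: ", bits, "-bit input rescaled to 8-bit (x/257, rounded)")
  }
  # readTIFF normalises to [0,1]; round(v*255) == round(raw/257) for 16-bit
  # inputs because 65535/257 = 255 exactly.
  planes <- lapply(slices, function(s) {
    a <- array(as.integer(round(s[, , 1:3] * 255)), dim = c(dim(s)[1:2], 3L))
    a
  })
  new_rgb_stack(planes, source_path = path, bits_per_sample = bits)
}

new_rgb_stack <- function(planes, source_path = NA_character_,
                          bits_per_sample = 8L) {
  d <- dim(planes[[1]])
  structure(
    list(planes = planes, height = d[1], width = d[2],
         n_slices = length(planes), bits_per_sample = bits_per_sample,
         source_path = source_path),
    class = "rgb_stack"
  )
}

#' @export
print.rgb_stack <- function(x, ...) {
  cat(sprintf("<rgb_stack> %d x %d px, %d slice(s), 8-bit (source %s-bit)\n",
              x$height, x$width, x$n_slices, x$bits_per_sample))
  invisible(x)
}

#' Write an RGB stack to a baseline TIFF
#'
#' Inverse of [read_rgb_stack()] for 8-bit stacks; the round trip is
#' pixel-identical. Used by the synthetic-image generator and useful for
#' archiving intermediate images.
#'
#' @param stack An `rgb_stack` (or a single `h x w x 3` array in 0--255).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_rgb_stack <- function(stack, path) {
  if (is.array(stack) && length(dim(stack)) == 3L) {
    stack <- new_rgb_stack(list(stack))
  }
  stopifnot(inherits(stack, "rgb_stack"))
  imgs <- lapply(stack$planes, function(p) {
    storage.mode(p) <- "double"
    p / 255
  })
  if (length(imgs) == 1L) imgs <- imgs[[1]]
  tiff::writeTIFF(imgs, path, bits.per.sample = 8L)
  invisible(path)
}

#' Split an RGB stack into red, green and blue channel images
#'
#' Reduces the stack to one analysis plane per colour. With
#' `slice_policy = "max"` (the default) each output pixel is the per-channel
#' maximum across slices — the usual projection for nuclei in thin tissue.
#' With `slice_policy = "single"` the 1-based `slice` index selects one plane.
#'
#' @param stack An `rgb_stack` from [read_rgb_stack()] or the generator.
#' @param slice_policy `"max"` (maximum projection) or `"single"`.
#' @param slice 1-based slice index, required when `slice_policy = "single"`.
#' @return Named list with elements `red`, `green`, `blue`, each a
#'   `channel_image` (integer matrix in 0--255 with `channel` and `source`
#'   attributes; row = y, column = x, origin top-left).
#' @export
split_channels <- function(stack, slice_policy = c("max", "single"),
                           slice = NULL) {
  stopifnot(inherits(stack, "rgb_stack"))
  slice_policy <- match.arg(slice_policy)
  if (slice_policy == "single") {
    if (is.null(slice) || slice < 1L || slice > stack$n_slices) {
      stop("input error: slice index ", slice %||% "NULL",
           " out of range 1..", stack$n_slices)
    }
    arr <- stack$planes[[slice]]
    chans <- lapply(1:3, function(k) arr[, , k])
  } else {
    chans <- lapply(1:3, function(k) {
      acc <- stack$planes[[1]][, , k]
      for (s in seq_len(stack$n_slices)[-1]) {
        acc <- pmax(acc, stack$planes[[s]][, , k])
      }
      acc
    })
  }
  names(chans) <- c("red", "green", "blue")
  Map(function(m, nm) channel_image(m, nm, stack$source_path),
      chans, names(chans))
}

#' Construct a channel image
#'
#' A channel image is an integer matrix of intensities in 0--255; rows are y
#' (top to bottom), columns are x (left to right). Pixel coordinates reported
#' by the package (centroids, polygon vertices) are 0-based with the origin
#' at the top-left pixel centre.
#'
#' @param values Numeric matrix of intensities in `[0, 255]`.
#' @param channel Channel name: `"red"`, `"green"` or `"blue"`.
#' @param source Path of the source image (optional, for provenance).
#' @return The matrix with class `channel_image`.
#' @export
channel_image <- function(values, channel = NA_character_,
                          source = NA_character_) {
  stopifnot(is.matrix(values))
  storage.mode(values) <- "integer"
  structure(values, channel = channel, source = source,
            class = c("channel_image", class(values)))
}

#' @export
print.channel_image <- function(x, ...) {
  cat(sprintf("<channel_image> %s, %d x %d px, range %d..%d\n",
              attr(x, "channel"), nrow(x), ncol(x), min(x), max(x)))
  invisible(x)
}

# strip channel_image class for matrix maths
as_intensity <- function(x) {
  m <- unclass(x)
  attr(m, "channel") <- NULL
  attr(m, "source") <- NULL
  storage.mode(m) <- "double"
  m
}

#' Write per-nucleus quantification results to CSV
#'
#' Writes one file per image with the fixed header
#' `image,roi_id,area_px,mean_raw,mean_bg,mean_corrected,centroid_x,centroid_y`
#' (RFC 4180, UTF-8). After the per-ROI rows a single summary row is appended
#' with `roi_id = "summary"`, carrying the ROI count in `area_px`, the shared
#' background in `mean_bg` and the image-level unweighted mean of
#' `mean_corrected`; its other fields are empty.
#'
#' @param results A quantification table from [quantify_image()] (class
#'   `fq_quant`), possibly with zero rows.
#' @param out_dir Writable output directory.
#' @param image_id Image identifier used for the file name; defaults to the
#'   table's own id.
#' @return The written file path.
#' @export
write_results_csv <- function(results, out_dir, image_id = NULL) {
  if (!dir.exists(out_dir)) {
    stop("I/O error: output directory does not exist: ", out_dir)
  }
  image_id <- image_id %||% attr(results, "image_id") %||% "image"
  smry <- glance(results)
  cols <- c("image", "roi_id", "area_px", "mean_raw", "mean_bg",
            "mean_corrected", "centroid_x", "centroid_y")
  body <- as.data.frame(results)[, cols, drop = FALSE]
  body$roi_id <- as.character(body$roi_id)
  summary_row <- data.frame(
    image = image_id, roi_id = "summary", area_px = smry$n_rois,
    mean_raw = NA_real_, mean_bg = smry$mean_bg,
    mean_corrected = smry$mean_corrected_mean,
    centroid_x = NA_real_, centroid_y = NA_real_
  )
  out <- rbind(body, summary_row)
  path <- file.path(out_dir, paste0(image_id, ".csv"))
  readr::write_csv(out, path, na = "")
  path
}
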