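#' Define the analysed tissue region
#'
#' A selection region restricts every downstream step — thresholding,
#' particle analysis and background estimation — to the tissue of interest
#' (e.g. the ventral ganglion). It is either a simple polygon given by its
#' vertices or the whole image.
#'
#' Vertices are `(x, y)` pixel coordinates, 0-based, origin at the top-left
#' pixel centre. Membership of a pixel uses the even-odd rule on pixel
#' centres, with points on the polygon boundary counted as inside.
#'
#' @param vertices A two-column matrix (or data frame / list of pairs) of
#'   polygon vertices, at least 3. Omit (or `NULL`) for the whole image.
#' @return A `selection_region` object.
#' @examples
#' sel <- selection_region(rbind(c(2, 2), c(20, 2), c(20, 20), c(2, 20)))
#' whole <- whole_image()
#' @export
selection_region <- function(vertices = NULL) {
  if (is.null(vertices)) return(whole_image())
  if (is.data.frame(vertices)) vertices <- as.matrix(vertices)
  if (is.list(vertices) && !is.matrix(vertices)) {
    vertices <- do.call(rbind, lapply(vertices, as.numeric))
  }
  stopifnot(is.matrix(vertices), ncol(vertices) == 2)
  if (nrow(vertices) < 3) {
    stop("input error: a polygonal selection needs at least 3 vertices")
  }
  storage.mode(vertices) <- "double"
  colnames(vertices) <- c("x", "y")
  structure(list(type = "polygon", vertices = vertices),
            class = "selection_region")
}

#' @rdname selection_region
#' @export
whole_image <- function() {
  structure(list(type = "whole_image", vertices = NULL),
            class = "selection_region")
}

#' @export
print.selection_region <- function(x, ...) {
  if (x$type == "whole_image") cat("<selection_region> whole image\n")
  else cat(sprintf("<selection_region> polygon, %d vertices\n",
                   nrow(x$vertices)))
  invisible(x)
}

# Shoelace area of the polygon (in px^2); 0 for degenerate selections.
polygon_area <- function(v) {
  n <- nrow(v)
  j <- c(n, seq_len(n - 1))
  abs(sum(v[j, 1] * v[, 2] - v[, 1] * v[j, 2])) / 2
}

#' Rasterise a selection region to a pixel mask
#'
#' Evaluates the even-odd rule at every pixel centre; boundary points count
#' as inside. Vertices outside the image are clipped to the image bounds
#' with a warning.
#'
#' @param selection A [selection_region()].
#' @param dim Image dimensions `c(height, width)` in pixels.
#' @return Logical matrix of the given dimensions, `TRUE` inside.
#' @export
selection_mask <- function(selection, dim) {
  stopifnot(inherits(selection, "selection_region"), length(dim) >= 2)
  h <- as.integer(dim[1]); w <- as.integer(dim[2])
  if (selection$type == "whole_image") return(matrix(TRUE, h, w))
  v <- selection$vertices
  if (any(v[, 1] < 0 | v[, 1] > w - 1 | v[, 2] < 0 | v[, 2] > h - 1)) {
    warning("selection vertices outside image bounds were clipped")
    v[, 1] <- pmin(pmax(v[, 1], 0), w - 1)
    v[, 2] <- pmin(pmax(v[, 2], 0), h - 1)
  }
  if (polygon_area(v) <= 0) {
    stop("input error: degenerate selection polygon (zero area)")
  }
  # pixel centres, column-major to match R matrix layout
  px <- rep(0:(w - 1), each = h)
  py <- rep(0:(h - 1), times = w)
  inside <- rep(FALSE, h * w)
  on_edge <- rep(FALSE, h * w)
  eps <- 1e-9
  n <- nrow(v)
  j <- n
  for (i in seq_len(n)) {
    xi <- v[i, 1]; yi <- v[i, 2]
    xj <- v[j, 1]; yj <- v[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    # boundary: collinear with the edge and within its bounding box
    cross <- (px - xi) * (yj - yi) - (py - yi) * (xj - xi)
    seg_len <- sqrt((xj - xi)^2 + (yj - yi)^2)
    on_seg <- abs(cross) <= eps * max(1, seg_len) &
      px >= pmin(xi, xj) - eps & px <= pmax(xi, xj) + eps &
      py >= pmin(yi, yj) - eps & py <= pmax(yi, yj) + eps
    on_edge <- on_edge | on_seg
    j <- i
  }
  matrix(inside | on_edge, h, w)
}

#' Zero all pixels outside the selection region
#'
#' The first pipeline step: intensities outside the drawn selection are set
#' to 0 so that thresholding and particle analysis see only the tissue of
#' interest. Pixels inside are unchanged.
#'
#' @param channel A [channel_image()].
#' @inheritParams selection_mask
#' @return A `channel_image` of the same dimensions.
#' @export
clear_outside_selection <- function(channel, selection) {
  m <- selection_mask(selection, dim(channel))
  out <- unclass(channel)
  out[!m] <- 0L
  channel_image(out, attr(channel, "channel"), attr(channel, "source"))
}

#' Read a polygon selection from an ImageJ .roi file
#'
#' Minimal read-only support for the standard ImageJ ROI binary format,
#' covering polygon, freehand and traced outline types. Coordinates are
#' returned 0-based in image pixels.
#'
#' @param path Path to a `.roi` file.
#' @return A polygonal [selection_region()].
#' @export
read_imagej_roi <- function(path) {
  if (!file.exists(path)) stop("input error: file not found: ", path)
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 64 || rawToChar(raw[1:4]) != "Iout") {
    stop("format error: not an ImageJ .roi file (missing 'Iout' magic)")
  }
  u16 <- function(off) {  # big-endian unsigned short at 0-based byte offset
    as.integer(raw[off + 1]) * 256L + as.integer(raw[off + 2])
  }
  s16 <- function(off) {  # signed
    v <- u16(off); if (v >= 32768L) v - 65536L else v
  }
  type <- as.integer(raw[7])        # byte 6: roi type
  if (!type %in% c(0L, 7L, 8L)) {
    stop("format error: unsupported ROI type ", type,
         " (only polygon/freehand/traced outlines are read)")
  }
  top <- s16(8); left <- s16(10)
  n <- u16(16)
  if (n < 3) stop("input error: ROI polygon has fewer than 3 vertices")
  xs <- vapply(seq_len(n), function(i) s16(64 + 2 * (i - 1)), integer(1))
  ys <- vapply(seq_len(n), function(i) s16(64 + 2 * n + 2 * (i - 1)), integer(1))
  selection_region(cbind(x = left + xs, y = top + ys))
}
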