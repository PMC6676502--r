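#' Particle filter settings
#'
#' Filters applied by [analyze_particles()], following the ImageJ
#' analyze-particles conventions: components are 8-connected and kept when
#' their area (in px^2) and circularity (`4*pi*area / perimeter^2`, clamped
#' at 1) fall inside the given closed intervals. The watershed/dilate flags
#' are consumed by [quantify_image()], which applies dilation first, then
#' watershed, then the particle analysis.
#'
#' The numeric defaults are implementation defaults chosen for
#' immunostained motor-neuron nuclei at typical confocal sampling (nuclei a
#' few hundred px^2, roundish); they are not derived from any reference
#' dataset and should be tuned to the object size and resolution at hand.
#'
#' @param min_area,max_area Area bounds in px^2.
#' @param min_circ,max_circ Circularity bounds in `[0, 1]`.
#' @param apply_watershed Split touching blobs before analysis.
#' @param apply_dilate Dilate the mask before analysis.
#' @param dilate_iterations Iterations for [binary_dilate()].
#' @param exclude_edge_particles Drop particles touching the image border
#'   (off by default).
#' @return A `particle_filter` object.
#' @export
particle_filter <- function(min_area = 30, max_area = Inf,
                            min_circ = 0.3, max_circ = 1,
                            apply_watershed = FALSE, apply_dilate = FALSE,
                            dilate_iterations = 1L,
                            exclude_edge_particles = FALSE) {
  if (min_area > max_area) stop("input error: min_area > max_area")
  if (min_circ < 0 || max_circ > 1 || min_circ > max_circ) {
    stop("input error: circularity bounds must satisfy 0 <= min <= max <= 1")
  }
  if (dilate_iterations < 0) stop("input error: dilate_iterations < 0")
  structure(list(min_area = min_area, max_area = max_area,
                 min_circ = min_circ, max_circ = max_circ,
                 apply_watershed = isTRUE(apply_watershed),
                 apply_dilate = isTRUE(apply_dilate),
                 dilate_iterations = as.integer(dilate_iterations),
                 exclude_edge_particles = isTRUE(exclude_edge_particles)),
            class = "particle_filter")
}

# 8-connected component labelling via the pixel adjacency graph.
# Returns an integer matrix; labels are 1..k in raster-scan order (rows top
# to bottom, then left to right) of each component's first pixel.
label_components <- function(mask) {
  stopifnot(is.matrix(mask))
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  idx <- which(mask)
  if (!length(idx)) return(lab)
  id <- integer(h * w)
  id[idx] <- seq_along(idx)
  rr <- ((idx - 1L) %% h) + 1L
  cc <- ((idx - 1L) %/% h) + 1L
  edges <- vector("list", 4)
  shifts <- list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))
  for (k in seq_along(shifts)) {
    s <- shifts[[k]]
    r2 <- rr + s[1]; c2 <- cc + s[2]
    ok <- r2 >= 1L & r2 <= h & c2 >= 1L & c2 <= w
    j <- (c2[ok] - 1L) * h + r2[ok]
    keep <- mask[j]
    if (any(keep)) edges[[k]] <- rbind(id[idx[ok][keep]], id[j[keep]])
  }
  ev <- as.integer(unlist(edges))
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(ev)) g <- igraph::add_edges(g, ev)
  memb <- igraph::components(g)$membership
  # renumber components by raster order of their first pixel
  raster_key <- (rr - 1L) * w + cc
  first_key <- vapply(split(raster_key, memb), min, numeric(1))
  new_id <- integer(length(first_key))
  new_id[order(first_key)] <- seq_along(first_key)
  lab[idx] <- new_id[memb]
  lab
}

# Moore-neighbour boundary trace of a single-particle mask (padded with a
# FALSE ring). Returns counts of straight and diagonal chain-code moves.
trace_moves <- function(sub) {
  h <- nrow(sub); w <- ncol(sub)
  start <- NULL
  for (r in seq_len(h)) {
    cc <- which(sub[r, ])
    if (length(cc)) { start <- c(r, cc[1]); break }
  }
  # clockwise on screen (y down): E, SE, S, SW, W, NW, N, NE
  dirs <- matrix(c(0, 1, 1, 1, 1, 0, 1, -1, 0, -1, -1, -1, -1, 0, -1, 1),
                 ncol = 2, byrow = TRUE)
  p <- start
  d_arr <- 7L  # makes the first scan start at NW, just after the W backtrack
  moves <- integer(0)
  first <- NULL
  max_iter <- 8L * (sum(sub) + 4L) * 4L
  for (iter in seq_len(max_iter)) {
    found <- FALSE
    scan0 <- (d_arr + 6L) %% 8L
    for (k in 0:7) {
      d <- (scan0 + k) %% 8L
      q <- p + dirs[d + 1L, ]
      if (sub[q[1], q[2]]) { found <- TRUE; break }
    }
    if (!found) break  # isolated pixel
    if (is.null(first)) {
      first <- d
    } else if (p[1] == start[1] && p[2] == start[2] && d == first) {
      break  # back at the start about to repeat the first move
    }
    moves <- c(moves, d)
    p <- p + dirs[d + 1L, ]
    d_arr <- d
  }
  c(straight = sum(moves %% 2L == 0L), diagonal = sum(moves %% 2L == 1L))
}

# Chain-code perimeter with the corner-corrected weights used by ImageJ's
# traced-outline perimeter (Kulpa's estimator): straight moves 0.948,
# diagonal moves 1.340. A single pixel counts as a unit square.
particle_perimeter <- function(sub) {
  mv <- trace_moves(sub)
  if (sum(mv) == 0) return(4 * 0.948)
  0.948 * mv[["straight"]] + 1.340 * mv[["diagonal"]]
}

#' Connected-component particle analysis
#'
#' Labels the 8-connected components of a binary mask, measures each one,
#' and keeps those passing the area and circularity filters. Measurements
#' follow the ImageJ conventions: area is the pixel count, the perimeter is
#' a corner-corrected boundary-walk (chain code) estimate of the outer
#' boundary length, and circularity is `4*pi*area / perimeter^2` clamped at
#' 1 (tiny particles can exceed 1 numerically). Surviving particles are
#' numbered 1..k in raster-scan order of their first pixel.
#'
#' @param mask Logical matrix (any dilation/watershed already applied).
#' @param filter A [particle_filter()].
#' @return A tibble of class `fq_particles` with one row per particle:
#'   `label`, `area`, `perimeter`, `circularity`, `centroid_x`, `centroid_y`
#'   (0-based pixel coordinates), `bbox_x0`, `bbox_y0`, `bbox_x1`, `bbox_y1`
#'   (inclusive), and `pixels`, a list column of linear indices into the
#'   image matrix. The mask dimensions travel along as attribute
#'   `dim_image`.
#' @export
analyze_particles <- function(mask, filter = particle_filter()) {
  stopifnot(is.matrix(mask), inherits(filter, "particle_filter"))
  h <- nrow(mask); w <- ncol(mask)
  lab <- label_components(mask)
  n <- max(lab)
  rows <- vector("list", n)
  for (l in seq_len(n)) {
    px <- which(lab == l)
    r <- ((px - 1L) %% h) + 1L
    cc <- ((px - 1L) %/% h) + 1L
    area <- length(px)
    if (area < filter$min_area || area > filter$max_area) next
    if (filter$exclude_edge_particles &&
        (min(r) == 1L || max(r) == h || min(cc) == 1L || max(cc) == w)) next
    r0 <- min(r); r1 <- max(r); c0 <- min(cc); c1 <- max(cc)
    sub <- matrix(FALSE, r1 - r0 + 3L, c1 - c0 + 3L)
    sub[cbind(r - r0 + 2L, cc - c0 + 2L)] <- TRUE
    per <- particle_perimeter(sub)
    circ <- min(1, 4 * pi * area / per^2)
    if (circ < filter$min_circ || circ > filter$max_circ) next
    rows[[l]] <- tibble::tibble(
      label = NA_integer_, area = area, perimeter = per, circularity = circ,
      centroid_x = mean(cc - 1L), centroid_y = mean(r - 1L),
      bbox_x0 = c0 - 1L, bbox_y0 = r0 - 1L, bbox_x1 = c1 - 1L,
      bbox_y1 = r1 - 1L, pixels = list(px)
    )
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(
      label = integer(), area = integer(), perimeter = double(),
      circularity = double(), centroid_x = double(), centroid_y = double(),
      bbox_x0 = integer(), bbox_y0 = integer(), bbox_x1 = integer(),
      bbox_y1 = integer(), pixels = list()
    )
  } else {
    out$label <- seq_len(nrow(out))
  }
  attr(out, "dim_image") <- c(h, w)
  class(out) <- c("fq_particles", class(out))
  out
}

#' Keep or drop particles by label
#'
#' Headless counterpart of the interactive "inspect and correct ROIs" step:
#' labels in `exclude_ids` are removed; when `include_ids` is non-empty only
#' those labels are kept. A label appearing in both lists is a conflict and
#' is refused rather than resolved silently.
#'
#' @param particles An `fq_particles` table from [analyze_particles()].
#' @param include_ids,exclude_ids Integer label vectors (either may be
#'   empty or `NULL`).
#' @return The filtered `fq_particles` table (labels unchanged).
#' @export
edit_particles <- function(particles, include_ids = NULL, exclude_ids = NULL) {
  include_ids <- as.integer(include_ids %||% integer())
  exclude_ids <- as.integer(exclude_ids %||% integer())
  unknown <- setdiff(c(include_ids, exclude_ids), particles$label)
  if (length(unknown)) {
    stop("input error: unknown particle id(s): ",
         paste(unknown, collapse = ", "))
  }
  both <- intersect(include_ids, exclude_ids)
  if (length(both)) {
    stop("input error: id(s) listed as both include and exclude: ",
         paste(both, collapse = ", "))
  }
  keep <- !(particles$label %in% exclude_ids)
  if (length(include_ids)) keep <- keep & particles$label %in% include_ids
  particles[keep, , drop = FALSE]
}
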