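#' Specification for a synthetic two-channel nucleus image
#'
#' Describes a ground-truth image emulating an immunostained ganglion:
#' disk-shaped nuclei of known marker and query intensity over a uniform
#' background, with optional additive Gaussian noise. The marker plane is
#' written to the red sample of an RGB stack and the query plane to the
#' green sample (blue is zero), mirroring the pipeline's RGB input
#' contract. Nuclei are hard disks kept at a minimum centre spacing so
#' particle counts have unambiguous ground truth; set `allow_touching` to
#' place merged blobs on purpose (to exercise the watershed).
#'
#' Intensity defaults emulate crisp nuclear immunostaining within the 8-bit
#' dynamic range: marker nuclei at 200 over a background of 20, query means
#' around 120, nucleus radii 5--8 px in a 128 x 128 field.
#'
#' @param image_size `c(height, width)` in pixels.
#' @param n_nuclei Number of nuclei to place.
#' @param radius_range `c(min, max)` nucleus radius in px.
#' @param marker_intensity Marker-channel disk level, must exceed the
#'   background.
#' @param query_mean Mean query-channel level per nucleus: `c(mu, sd)` for a
#'   Gaussian draw per nucleus.
#' @param query_means Optional explicit per-nucleus query means (overrides
#'   `query_mean`; length `n_nuclei`).
#' @param background_level Background level for both channels.
#' @param noise_sd Additive Gaussian noise SD (0 = noiseless); applied
#'   before 8-bit clipping.
#' @param min_center_spacing Minimum distance between nucleus centres;
#'   default `2 * max(radius_range) + 3` (non-overlapping, non-touching).
#' @param allow_touching If `TRUE`, spacing defaults to
#'   `1.6 * max(radius_range)` so neighbouring disks merge into blobs.
#' @param seed Integer seed making the image deterministic; `NULL` uses the
#'   current RNG stream.
#' @return A `synth_spec` object (JSON-serialisable via
#'   [jsonlite::toJSON()] on `unclass()`).
#' @export
synth_spec <- function(image_size = c(128, 128), n_nuclei = 10,
                       radius_range = c(5, 8), marker_intensity = 200,
                       query_mean = c(mu = 120, sd = 20), query_means = NULL,
                       background_level = 20, noise_sd = 0,
                       min_center_spacing = NULL, allow_touching = FALSE,
                       seed = NULL) {
  if (background_level >= marker_intensity) {
    stop("input error: background_level must be below marker_intensity")
  }
  if (length(radius_range) == 1) radius_range <- rep(radius_range, 2)
  if (!is.null(query_means) && length(query_means) != n_nuclei) {
    stop("input error: query_means must have length n_nuclei")
  }
  spacing <- min_center_spacing %||%
    if (allow_touching) 1.6 * max(radius_range) else 2 * max(radius_range) + 3
  structure(
    list(image_size = as.integer(image_size), n_nuclei = as.integer(n_nuclei),
         radius_range = radius_range, marker_intensity = marker_intensity,
         query_mean = c(mu = unname(query_mean[1]),
                        sd = unname(query_mean[2])),
         query_means = query_means, background_level = background_level,
         noise_sd = noise_sd, min_center_spacing = spacing,
         allow_touching = isTRUE(allow_touching), seed = seed),
    class = "synth_spec"
  )
}

#' @export
print.synth_spec <- function(x, ...) {
  cat(sprintf(
    "<synth_spec> %dx%d px, %d nuclei r[%g,%g], marker %g / bg %g, noise sd %g\n",
    x$image_size[1], x$image_size[2], x$n_nuclei, x$radius_range[1],
    x$radius_range[2], x$marker_intensity, x$background_level, x$noise_sd))
  invisible(x)
}

# Rejection-sample nucleus centres at the required spacing (bounded).
place_centers <- function(h, w, n, r_max, spacing, max_attempts = 10000L) {
  centers <- matrix(NA_real_, n, 2)
  placed <- 0L
  margin <- r_max + 1
  for (att in seq_len(max_attempts)) {
    if (placed == n) break
    cand <- c(stats::runif(1, margin, w - 1 - margin),
              stats::runif(1, margin, h - 1 - margin))
    if (placed == 0L ||
        min(sqrt((centers[seq_len(placed), 1] - cand[1])^2 +
                 (centers[seq_len(placed), 2] - cand[2])^2)) >= spacing) {
      placed <- placed + 1L
      centers[placed, ] <- cand
    }
  }
  if (placed < n) {
    stop("input error: could not place ", n, " nuclei at spacing ", spacing,
         " in ", h, "x", w, " px; use fewer or smaller nuclei")
  }
  centers
}

#' Generate a synthetic two-channel image with ground truth
#'
#' Renders the image described by a [synth_spec()]: the marker plane holds
#' disks at `marker_intensity`, the query plane holds the same disks at
#' their per-nucleus true query means, both over `background_level`.
#' Gaussian noise (if any) is added before rounding and clipping to
#' `[0, 255]`; the number of clipped pixels is recorded. Deterministic for
#' a fixed `spec$seed`.
#'
#' @param spec A [synth_spec()].
#' @return List with `stack` (an in-memory `rgb_stack`) and `truth`, a list
#'   holding the `nuclei` tibble (`id`, `x`, `y`, `radius`, `query_mean`),
#'   `background_level`, the integer `label_image`, and `n_clipped`.
#' @export
generate_image <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  local_seed(spec$seed, {
    h <- spec$image_size[1]; w <- spec$image_size[2]
    n <- spec$n_nuclei
    marker <- matrix(spec$background_level, h, w)
    query <- matrix(spec$background_level, h, w)
    label <- matrix(0L, h, w)
    nuclei <- tibble::tibble(id = integer(), x = double(), y = double(),
                             radius = double(), query_mean = double())
    if (n > 0) {
      centers <- place_centers(h, w, n, max(spec$radius_range),
                               spec$min_center_spacing)
      radii <- stats::runif(n, spec$radius_range[1], spec$radius_range[2])
      qmeans <- spec$query_means %||%
        rnorm(n, spec$query_mean[["mu"]], spec$query_mean[["sd"]])
      px <- rep(0:(w - 1), each = h)
      py <- rep(0:(h - 1), times = w)
      for (i in seq_len(n)) {
        disk <- (px - centers[i, 1])^2 + (py - centers[i, 2])^2 <= radii[i]^2
        marker[disk] <- spec$marker_intensity
        query[disk] <- qmeans[i]
        label[disk] <- i
      }
      nuclei <- tibble::tibble(id = seq_len(n), x = centers[, 1],
                               y = centers[, 2], radius = radii,
                               query_mean = qmeans)
    }
    if (spec$noise_sd > 0) {
      marker <- marker + rnorm(length(marker), 0, spec$noise_sd)
      query <- query + rnorm(length(query), 0, spec$noise_sd)
    }
    n_clipped <- sum(marker < 0 | marker > 255) + sum(query < 0 | query > 255)
    marker <- pmin(pmax(round(marker), 0), 255)
    query <- pmin(pmax(round(query), 0), 255)
    plane <- array(0L, dim = c(h, w, 3L))
    plane[, , 1] <- as.integer(marker)
    plane[, , 2] <- as.integer(query)
    list(
      stack = new_rgb_stack(list(plane), source_path = "<synthetic>"),
      truth = list(nuclei = nuclei,
                   background_level = spec$background_level,
                   label_image = label, n_clipped = n_clipped)
    )
  })
}

#' Generate a two-group synthetic experiment on disk
#'
#' Writes `n_images_per_group` TIFFs per group (file names
#' `<group>_<index>.tif`) plus a `manifest.csv` describing each image's
#' ground truth. Per-image seeds are derived deterministically from
#' `base_seed` plus the image index, so the whole experiment is reproducible
#' from one integer.
#'
#' @param control_spec,experimental_spec [synth_spec()]s for the two groups
#'   (their `seed` fields are overridden per image).
#' @param n_images_per_group Images per group.
#' @param out_dir Output directory (created if needed).
#' @param base_seed Integer base seed.
#' @param group_names Character vector of length 2, default
#'   `c("control", "experimental")`.
#' @return The manifest tibble (`file`, `group`, `n_nuclei`,
#'   `true_query_mean`, `true_background`, `true_corrected_mean`), with the
#'   manifest path in attribute `path`.
#' @export
generate_experiment <- function(control_spec, experimental_spec,
                                n_images_per_group = 8, out_dir,
                                base_seed = 1L,
                                group_names = c("control", "experimental")) {
  stopifnot(inherits(control_spec, "synth_spec"),
            inherits(experimental_spec, "synth_spec"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  specs <- list(control_spec, experimental_spec)
  rows <- list()
  k <- 0L
  for (g in 1:2) {
    for (i in seq_len(n_images_per_group)) {
      k <- k + 1L
      spec <- specs[[g]]
      spec$seed <- as.integer(base_seed) + k
      img <- generate_image(spec)
      file <- sprintf("%s_%02d.tif", group_names[g], i)
      write_rgb_stack(img$stack, file.path(out_dir, file))
      rows[[k]] <- tibble::tibble(
        file = file, group = group_names[g],
        n_nuclei = nrow(img$truth$nuclei),
        true_query_mean = mean(img$truth$nuclei$query_mean),
        true_background = img$truth$background_level,
        true_corrected_mean = mean(img$truth$nuclei$query_mean) -
          img$truth$background_level
      )
    }
  }
  manifest <- dplyr::bind_rows(rows)
  path <- file.path(out_dir, "manifest.csv")
  readr::write_csv(manifest, path)
  attr(manifest, "path") <- path
  manifest
}
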