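#' Threshold specification
#'
#' Describes how the marker channel is binarised: either a manual intensity
#' window `[min_level, max_level]` (both bounds inclusive, 0--255) or an
#' automatically computed level (see [auto_threshold()]).
#'
#' @param min_level,max_level Integer levels in `[0, 255]`, `min <= max`.
#' @param mode `"manual"` or `"auto"`; [auto_threshold()] resolves `"auto"`
#'   into a manual-equivalent spec.
#' @param method Auto-threshold algorithm the levels came from (recorded for
#'   provenance): `"isodata"` (the ImageJ default variant) or `"otsu"`.
#' @return A `threshold_spec` object.
#' @export
threshold_spec <- function(min_level = 0L, max_level = 255L, mode = "manual",
                           method = NA_character_) {
  min_level <- as.integer(min_level); max_level <- as.integer(max_level)
  if (is.na(min_level) || is.na(max_level) ||
      min_level < 0L || max_level > 255L || min_level > max_level) {
    stop("input error: threshold levels must satisfy 0 <= min <= max <= 255")
  }
  structure(list(mode = mode, min_level = min_level, max_level = max_level,
                 method = method),
            class = "threshold_spec")
}

#' @export
print.threshold_spec <- function(x, ...) {
  cat(sprintf("<threshold_spec> %s [%d, %d]%s\n", x$mode, x$min_level,
              x$max_level,
              if (!is.na(x$method)) paste0(" (", x$method, ")") else ""))
  invisible(x)
}

# 256-bin histogram of the in-selection pixels of a channel
selection_histogram <- function(channel, selection) {
  m <- selection_mask(selection, dim(channel))
  vals <- unclass(channel)[m]
  tabulate(vals + 1L, nbins = 256L)
}

# Iterative isodata threshold on a 256-bin histogram: the level t such that
# t is the rounded midpoint of the means below (< t) and at-or-above t.
isodata_level <- function(counts) {
  v <- 0:255
  t <- round(sum(v * counts) / sum(counts))
  repeat {
    lo <- v < t
    m_lo <- sum(v[lo] * counts[lo]) / sum(counts[lo])
    m_hi <- sum(v[!lo] * counts[!lo]) / sum(counts[!lo])
    t_new <- round((m_lo + m_hi) / 2)
    if (is.na(t_new) || t_new == t) break
    t <- t_new
  }
  as.integer(t)
}

# Otsu threshold: cut point t (classes < t and >= t) maximising the
# between-class variance; ties broken towards the smallest level.
otsu_level <- function(counts) {
  v <- 0:255
  n <- sum(counts)
  w0 <- cumsum(counts)            # weight of class {0..t}
  s0 <- cumsum(v * counts)
  total <- s0[256]
  # candidate cut points t = 1..255 split {0..t-1} vs {t..255}
  w_lo <- w0[1:255]
  w_hi <- n - w_lo
  mu_lo <- s0[1:255] / w_lo
  mu_hi <- (total - s0[1:255]) / w_hi
  bcv <- w_lo * w_hi * (mu_lo - mu_hi)^2
  bcv[w_lo == 0 | w_hi == 0] <- -Inf
  as.integer(which.max(bcv))      # which.max takes the first (smallest) tie
}

#' Compute an automatic threshold from the in-selection histogram
#'
#' Builds the 256-bin histogram of the pixels inside the selection only —
#' cleared or out-of-selection pixels never influence the level — and
#' computes a single lower threshold level. The default algorithm is the
#' iterative intermeans ("isodata") method, the variant behind ImageJ's
#' default auto threshold; Otsu's between-class-variance maximiser is
#' selectable. The result is a manual-equivalent [threshold_spec()] with
#' `max_level = 255` and the method recorded.
#'
#' @inheritParams clear_outside_selection
#' @param method `"isodata"` (default) or `"otsu"`.
#' @return A `threshold_spec`.
#' @export
auto_threshold <- function(channel, selection = whole_image(),
                           method = c("isodata", "otsu")) {
  method <- match.arg(method)
  counts <- selection_histogram(channel, selection)
  if (sum(counts > 0) < 2) {
    stop("input error: in-selection intensity is constant; ",
         "use a manual threshold_spec instead")
  }
  level <- switch(method,
                  isodata = isodata_level(counts),
                  otsu = otsu_level(counts))
  threshold_spec(min_level = level, max_level = 255L, mode = "auto",
                 method = method)
}

#' Binarise a channel with a threshold window
#'
#' @inheritParams auto_threshold
#' @param spec A [threshold_spec()].
#' @return Logical matrix, `TRUE` where `min_level <= intensity <= max_level`
#'   and the pixel lies inside the selection.
#' @export
apply_threshold <- function(channel, spec, selection = whole_image()) {
  stopifnot(inherits(spec, "threshold_spec"))
  m <- selection_mask(selection, dim(channel))
  v <- unclass(channel)
  (v >= spec$min_level & v <= spec$max_level) & m
}
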